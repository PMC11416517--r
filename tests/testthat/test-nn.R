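test_that("He initialization has the right moments and determinism", {
  n_in <- 11520
  w <- he_init(c(100000, 1), n_in = n_in, seed = 6)
  target <- sqrt(2 / n_in)
  expect_lt(abs(sd(w) - target) / target, 0.05)
  expect_lt(abs(mean(w)), 3 * target / sqrt(1e5))
  expect_identical(he_init(c(10, 10), 5, seed = 2), he_init(c(10, 10), 5, seed = 2))
  expect_error(he_init(c(2, 2), 0), "fan-in")
})

test_that("activation functions follow their definitions", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(1000), 1)          # stable, no overflow
  expect_equal(sigmoid(-1000), 0)
  expect_equal(elu(0), 0)
  expect_equal(elu(1e-9), 1e-9)           # continuous at 0
  expect_equal(elu(-1e-9), -1e-9, tolerance = 1e-6)
  expect_equal(elu(-50), -1, tolerance = 1e-12)   # asymptote -alpha
  expect_equal(elu(-50, alpha = 2), -2, tolerance = 1e-10)
  expect_equal(elu(3), 3)
})

test_that("max pooling equals a brute-force window maximum", {
  withr::with_seed(10, {
    for (rep in 1:5) {
      x <- array(rnorm(4 * 4 * 4 * 2 * 2), c(4, 4, 4, 2, 2))
      r <- voxcnn:::maxpool3d_fwd_cpp(x, dim(x), 2L)
      y <- array(r$y, c(2, 2, 2, 2, 2))
      for (b in 1:2) for (c in 1:2) for (i in 1:2) for (j in 1:2) for (k in 1:2) {
        win <- x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j),
                 (2 * k - 1):(2 * k), c, b]
        expect_equal(y[i, j, k, c, b], max(win))
      }
    }
  })
})

test_that("3D convolution matches a direct sliding-window oracle", {
  withr::with_seed(11, {
    D <- 5; H <- 6; W <- 4; Ci <- 2; Co <- 2; B <- 2
    x <- array(rnorm(D * H * W * Ci * B), c(D, H, W, Ci, B))
    w <- array(rnorm(27 * Ci * Co), c(3, 3, 3, Ci, Co))
    b <- rnorm(Co)
    y <- voxcnn:::conv3d_fwd_cpp(x, dim(x), w, dim(w), b)
    dim(y) <- c(D - 2, H - 2, W - 2, Co, B)
    for (bb in 1:B) for (co in 1:Co) for (i in 1:(D - 2)) for (j in 1:(H - 2))
      for (k in 1:(W - 2)) {
        acc <- b[co]
        for (ci in 1:Ci) {
          acc <- acc + sum(x[i:(i + 2), j:(j + 2), k:(k + 2), ci, bb] *
                             w[, , , ci, co])
        }
        expect_equal(y[i, j, k, co, bb], acc, tolerance = 1e-12)
      }
  })
})

test_that("batch normalization standardizes, shifts and guards zero variance", {
  arch <- tiny_arch()
  model <- build_model(arch, seed = 1)
  x <- withr::with_seed(3, array(rnorm(6 * 10 * 10 * 4 * 3, 5, 2),
                                 c(6, 10, 10, 4, 3)))
  # locate the batchnorm op
  bn_i <- which(sapply(arch$ops, function(o) o$kind) == "batchnorm")[1]
  P <- model$params[[bn_i]]
  out <- voxcnn:::bn_reshape(x)
  # gamma=1, beta=0 training mode: per-channel mean ~0, var ~1
  fwd_bn <- function(gamma, beta, xin) {
    mu <- colMeans(xin); v <- colMeans(xin^2) - mu^2
    xhat <- sweep(sweep(xin, 2, mu), 2, 1 / sqrt(v + 1e-3), `*`)
    sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  }
  y <- fwd_bn(rep(1, 4), rep(0, 4), out)
  expect_equal(colMeans(y), rep(0, 4), tolerance = 1e-10)
  expect_equal(apply(y, 2, sd), rep(1, 4), tolerance = 0.05)
  y2 <- fwd_bn(rep(2, 4), rep(3, 4), y)
  expect_equal(colMeans(y2), rep(3, 4), tolerance = 1e-9)
  expect_equal(apply(y2, 2, sd), rep(2, 4), tolerance = 0.1)
  # constant channel: output ~ beta
  xc <- matrix(7, 100, 2)
  yc <- fwd_bn(c(1, 1), c(0.5, -0.5), xc)
  expect_equal(colMeans(yc), c(0.5, -0.5), tolerance = 1e-9)
})

test_that("backpropagation agrees with central finite differences", {
  arch <- architecture(input_shape = c(8L, 10L, 10L, 1L), filters = 2L,
                       dense_units = 4L, dropout_rate = 0)
  pc <- count_parameters(arch)
  expect_lt(pc$total, 1000)
  model <- build_model(arch, seed = 3)
  xs <- lapply(1:2, function(i) {
    a <- withr::with_seed(100 + i, array(rnorm(800), c(8, 10, 10, 1)))
    voxcnn:::new_volume_stack(a, paste0("F", i), "diseased", 8L)
  })
  yv <- c(1, 0)
  xb <- voxcnn:::stack_batch(xs)
  loss_of <- function(m) {
    fw <- voxcnn:::nn_forward(m, xb, training = TRUE)
    bce(yv, sigmoid(fw$logit)) + l2_penalty(m)
  }
  fw <- voxcnn:::nn_forward(model, xb, training = TRUE)
  bw <- voxcnn:::nn_backward(model, fw$caches,
                             (sigmoid(fw$logit) - yv) / 2)
  h <- 1e-5
  worst <- 0
  withr::with_seed(9, {
    for (i in seq_along(arch$ops)) {
      gi <- bw$param_grads[[i]]
      if (is.null(gi)) next
      op <- arch$ops[[i]]
      for (nm in names(gi)) {
        g <- gi[[nm]]
        if (nm == "W" && op$kind %in% c("conv3d", "dense")) {
          g <- g + 2 * op$l2 * model$params[[i]][[nm]]
        }
        for (s in sample(length(g), min(6, length(g)))) {
          mp <- model; mp$params[[i]][[nm]][s] <- mp$params[[i]][[nm]][s] + h
          mm <- model; mm$params[[i]][[nm]][s] <- mm$params[[i]][[nm]][s] - h
          fd <- (loss_of(mp) - loss_of(mm)) / (2 * h)
          worst <- max(worst, abs(fd - g[s]) /
                         max(abs(fd), abs(g[s]), 1e-8))
        }
      }
    }
  })
  expect_lt(worst, 1e-4)
})

test_that("the L2 penalty equals 0.05 times the summed squared weights", {
  model <- build_model(tiny_arch(), seed = 5)
  direct <- 0
  for (i in seq_along(model$arch$ops)) {
    if (model$arch$ops[[i]]$kind %in% c("conv3d", "dense")) {
      direct <- direct + 0.05 * sum(model$params[[i]]$W^2)
    }
  }
  expect_equal(l2_penalty(model), direct, tolerance = 1e-12)
})

test_that("prediction is a probability, deterministic, and shape-checked", {
  model <- build_model(tiny_arch(), seed = 7)
  s <- tiny_stack(55)
  p <- predict(model, s)
  expect_gt(p, 0); expect_lt(p, 1)
  expect_identical(predict(model, s), p)  # no dropout noise at inference
  zero <- voxcnn:::new_volume_stack(array(0, c(8, 12, 12, 1)), "z", NA, 1L)
  expect_true(is.finite(predict(model, zero)))
  wrong <- voxcnn:::new_volume_stack(array(0, c(4, 4, 4, 1)), "w", NA, 1L)
  expect_error(predict(model, wrong), "shape")
  expect_equal(predict(model, list(s, s, zero)),
               c(p, p, predict(model, zero)))
})
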