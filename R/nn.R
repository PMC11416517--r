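# The network engine: forward pass, hand-derived backward pass, and an Adam
# training loop with a reduce-on-plateau learning-rate schedule. Convolution
# and pooling kernels are compiled (src/nn_ops.cpp); batch normalization,
# dense layers, dropout and the optimizer are vectorized R. Gradient
# correctness is pinned by a finite-difference test on a small profile.

#' He (Kaiming) weight initialization
#'
#' Draws i.i.d. `Normal(0, sqrt(2 / n_in))` entries -- the variance-
#' preserving initialization for ELU/ReLU-family networks.
#'
#' @param dim Integer vector of tensor dimensions.
#' @param n_in Fan-in (number of inputs feeding one unit); must be >= 1.
#' @param seed Optional seed for a self-contained deterministic draw.
#' @return Array of the requested dimensions.
#' @export
he_init <- function(dim, n_in, seed = NULL) {
  if (n_in < 1) abort("he_init: fan-in must be >= 1")
  draw <- function() array(rnorm(prod(dim), 0, sqrt(2 / n_in)), dim)
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

#' Exponential linear unit
#'
#' `x` for `x > 0`, `alpha * (exp(x) - 1)` otherwise; continuous at 0 with
#' asymptote `-alpha`.
#'
#' @param x Numeric.
#' @param alpha Saturation scale (canonical 1).
#' @return Numeric of the same shape.
#' @export
elu <- function(x, alpha = 1) {
  ifelse(x > 0, x, alpha * (exp(pmin(x, 0)) - 1))
}

elu_grad <- function(z, alpha = 1) ifelse(z > 0, 1, alpha * exp(pmin(z, 0)))

#' Numerically stable logistic sigmoid
#'
#' @param x Numeric.
#' @return `1 / (1 + exp(-x))`, computed without overflow for large `|x|`.
#' @export
sigmoid <- function(x) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  e <- exp(x[!pos])
  out[!pos] <- e / (1 + e)
  out[is.na(x)] <- NA_real_
  dim(out) <- dim(x)
  out
}

.bn_eps <- 1e-3
.bn_momentum <- 0.99

#' Instantiate a model from an architecture specification
#'
#' Allocates and He-initializes all weight tensors (biases and batch-norm
#' shifts start at zero, scales at one).
#'
#' @param arch A [architecture()] specification.
#' @param seed Integer seed for the weight draws.
#' @return A `voxcnn_model`.
#' @export
build_model <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "voxcnn_architecture"))
  params <- with_local_seed(seed, {
    lapply(arch$ops, function(op) {
      switch(op$kind,
        conv3d = {
          f <- op$filters; cin <- op$in_channels
          list(W = he_init(c(3L, 3L, 3L, cin, f), n_in = 27L * cin),
               b = numeric(f))
        },
        batchnorm = list(gamma = rep(1, op$channels),
                         beta = numeric(op$channels),
                         run_mean = numeric(op$channels),
                         run_var = rep(1, op$channels)),
        dense = list(W = he_init(c(op$in_units, op$units), n_in = op$in_units),
                     b = numeric(op$units)),
        NULL
      )
    })
  })
  structure(list(arch = arch, params = params), class = "voxcnn_model")
}

# stack a list of volume_stacks into a (D,H,W,C,B) batch array
stack_batch <- function(stacks) {
  if (inherits(stacks, "volume_stack")) stacks <- list(stacks)
  d <- dim(stacks[[1]])
  x <- array(0, c(d, length(stacks)))
  for (i in seq_along(stacks)) x[, , , , i] <- stacks[[i]]
  x
}

bn_reshape <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 3, 5, 4)), ncol = d[4])
}

bn_unshape <- function(xm, d) {
  aperm(array(xm, c(d[1], d[2], d[3], d[5], d[4])), c(1, 2, 3, 5, 4))
}

# forward pass over the op list; returns logits, per-op caches, and the
# model (running statistics are updated when training). `capture` lists op
# indices whose output activation should be kept (for Grad-CAM).
nn_forward <- function(model, x, training = FALSE, capture = integer(0)) {
  ops <- model$arch$ops
  caches <- vector("list", length(ops))
  acts <- list()
  a <- x
  for (i in seq_along(ops)) {
    op <- ops[[i]]
    P <- model$params[[i]]
    if (op$kind == "conv3d") {
      xdim <- dim(a)
      z <- conv3d_fwd_cpp(a, xdim, P$W, dim(P$W), P$b)
      dim(z) <- c(op$output_shape, xdim[5])
      caches[[i]] <- list(x = a, z = z)
      a <- elu(z)
    } else if (op$kind == "batchnorm") {
      d <- dim(a)
      xm <- bn_reshape(a)
      if (training) {
        mu <- colMeans(xm)
        v <- pmax(colMeans(xm^2) - mu^2, 0)
        model$params[[i]]$run_mean <- .bn_momentum * P$run_mean +
          (1 - .bn_momentum) * mu
        model$params[[i]]$run_var <- .bn_momentum * P$run_var +
          (1 - .bn_momentum) * v
      } else {
        mu <- P$run_mean
        v <- P$run_var
      }
      invstd <- 1 / sqrt(v + .bn_eps)
      xhat <- sweep(sweep(xm, 2, mu), 2, invstd, `*`)
      ym <- sweep(sweep(xhat, 2, P$gamma, `*`), 2, P$beta, `+`)
      caches[[i]] <- list(xhat = xhat, invstd = invstd, d = d,
                          training = training)
      a <- bn_unshape(ym, d)
    } else if (op$kind == "maxpool3d") {
      xdim <- dim(a)
      r <- maxpool3d_fwd_cpp(a, xdim, op$pool)
      caches[[i]] <- list(idx = r$idx, xlen = length(a), xdim = xdim)
      a <- r$y
      dim(a) <- c(op$output_shape, xdim[5])
    } else if (op$kind == "flatten") {
      d <- dim(a)
      caches[[i]] <- list(d = d)
      dim(a) <- c(prod(d[-length(d)]), d[length(d)])
    } else if (op$kind == "dense") {
      z <- crossprod(P$W, a) + P$b
      caches[[i]] <- list(x = a, z = z)
      a <- if (op$activation == "elu") elu(z) else z  # sigmoid applied at loss
    } else if (op$kind == "dropout") {
      if (training && op$rate > 0) {
        mask <- (matrix(runif(length(a)), nrow(a)) >= op$rate) / (1 - op$rate)
        caches[[i]] <- list(mask = mask)
        a <- a * mask
      } else {
        caches[[i]] <- list(mask = NULL)
      }
    }
    if (i %in% capture) acts[[as.character(i)]] <- a
  }
  list(logit = as.numeric(a), caches = caches, model = model, acts = acts)
}

# backward pass; dlogit is dL/dlogit (length B). Returns param grads and,
# when stop_at is given (an op index), the gradient w.r.t. that op's output
# instead of descending further.
nn_backward <- function(model, caches, dlogit, stop_at = 0L,
                        param_grads = TRUE) {
  ops <- model$arch$ops
  grads <- vector("list", length(ops))
  g <- matrix(dlogit, nrow = 1)
  for (i in rev(seq_along(ops))) {
    if (i <= stop_at) break
    op <- ops[[i]]
    P <- model$params[[i]]
    cc <- caches[[i]]
    if (op$kind == "dense") {
      dz <- if (op$activation == "elu") g * elu_grad(cc$z) else g
      if (param_grads) {
        grads[[i]] <- list(W = cc$x %*% t(dz), b = rowSums(dz))
      }
      g <- P$W %*% dz
    } else if (op$kind == "dropout") {
      if (!is.null(cc$mask)) g <- g * cc$mask
    } else if (op$kind == "flatten") {
      dim(g) <- cc$d
    } else if (op$kind == "maxpool3d") {
      dx <- maxpool3d_bwd_cpp(as.numeric(g), cc$idx, cc$xlen)
      dim(dx) <- cc$xdim
      g <- dx
    } else if (op$kind == "batchnorm") {
      d <- cc$d
      dym <- bn_reshape(g)
      if (param_grads) {
        grads[[i]] <- list(gamma = colSums(dym * cc$xhat),
                           beta = colSums(dym))
      }
      if (cc$training) {
        nr <- nrow(dym)
        m1 <- colMeans(dym)
        m2 <- colMeans(dym * cc$xhat)
        dxm <- sweep(sweep(dym, 2, m1) - sweep(cc$xhat, 2, m2, `*`),
                     2, P$gamma * cc$invstd, `*`)
      } else {
        dxm <- sweep(dym, 2, P$gamma * cc$invstd, `*`)
      }
      g <- bn_unshape(dxm, d)
    } else if (op$kind == "conv3d") {
      dz <- g * elu_grad(cc$z)
      r <- conv3d_bwd_cpp(cc$x, dim(cc$x), P$W, dim(P$W), dz)
      if (param_grads) {
        dw <- r$dw; dim(dw) <- dim(P$W)
        grads[[i]] <- list(W = dw, b = r$db)
      }
      dx <- r$dx
      dim(dx) <- dim(cc$x)
      g <- dx
    }
  }
  list(param_grads = grads, dx = g)
}

#' L2 penalty of a model
#'
#' `sum(l2 * w^2)` over all convolutional and dense weight tensors (biases
#' and batch-normalization parameters are not penalized).
#'
#' @param model A `voxcnn_model`.
#' @return Scalar penalty value.
#' @export
l2_penalty <- function(model) {
  tot <- 0
  for (i in seq_along(model$arch$ops)) {
    op <- model$arch$ops[[i]]
    if (op$kind %in% c("conv3d", "dense")) {
      tot <- tot + op$l2 * sum(model$params[[i]]$W^2)
    }
  }
  tot
}

#' Predict class probabilities for volume stacks
#'
#' Runs the network in inference mode (running batch-norm statistics, no
#' dropout) and returns the sigmoid output probability of the diseased
#' class.
#'
#' @param object A `voxcnn_model`.
#' @param newdata A `volume_stack` or list of them.
#' @param type `"prob"` for probabilities, `"class"` for thresholded 0/1
#'   labels.
#' @param threshold Decision threshold for `type = "class"`.
#' @param batch_size Stacks per forward batch.
#' @param ... Unused.
#' @return Numeric vector of probabilities (or 0/1 labels).
#' @export
predict.voxcnn_model <- function(object, newdata, type = c("prob", "class"),
                                 threshold = 0.5, batch_size = 8L, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "volume_stack")) newdata <- list(newdata)
  expect <- object$arch$input_shape
  probs <- numeric(length(newdata))
  for (start in seq(1, length(newdata), by = batch_size)) {
    idx <- start:min(start + batch_size - 1, length(newdata))
    for (s in newdata[idx]) {
      if (!identical(as.integer(dim(s)), as.integer(expect))) {
        abort(sprintf("stack shape (%s) does not match model input (%s)",
                      paste(dim(s), collapse = ","),
                      paste(expect, collapse = ",")))
      }
    }
    fw <- nn_forward(object, stack_batch(newdata[idx]), training = FALSE)
    probs[idx] <- sigmoid(fw$logit)
  }
  if (type == "class") as.integer(probs >= threshold) else probs
}

#' @export
predict.voxcnn_fit <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}

#' Training configuration
#'
#' @param optimizer `"adam"` or `"sgd"`.
#' @param learning_rate Initial learning rate (default 0.001, the value
#'   found optimal in the underlying study).
#' @param plateau_factor,plateau_patience,min_lr Reduce-on-plateau schedule:
#'   multiply the learning rate by `plateau_factor` when the monitored
#'   validation loss has not improved for `plateau_patience` epochs.
#' @param batch_size Stacks per gradient step.
#' @param epochs Training epochs.
#' @param decision_threshold Probability cutoff for the diseased class.
#' @param seed Seed covering shuffling, dropout and weight initialization.
#' @return A `train_config` list.
#' @export
train_config <- function(optimizer = c("adam", "sgd"), learning_rate = 0.001,
                         plateau_factor = 0.5, plateau_patience = 5L,
                         min_lr = 1e-5, batch_size = 2L, epochs = 100L,
                         decision_threshold = 0.5, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (learning_rate <= 0) abort("train_config: learning_rate must be > 0")
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 min_lr = min_lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 decision_threshold = decision_threshold,
                 seed = as.integer(seed)),
            class = "train_config")
}

.trainable_names <- function(kind) {
  switch(kind, conv3d = c("W", "b"), dense = c("W", "b"),
         batchnorm = c("gamma", "beta"), character(0))
}

#' Train a model with binary cross-entropy + L2 loss
#'
#' Minimizes mean binary cross-entropy plus the L2 weight penalty with Adam
#' (or plain SGD), reducing the learning rate on validation-loss plateaus.
#' Fully deterministic for a fixed seed and data order.
#'
#' @param model A `voxcnn_model` (see [build_model()]).
#' @param x,y Training stacks (list of `volume_stack`) and 0/1 labels.
#' @param x_val,y_val Optional validation stacks/labels; when absent the
#'   plateau schedule monitors the training loss.
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return A `voxcnn_fit`: `$model`, `$history` (per-epoch tibble with
#'   loss, learning rate and validation metrics), `$config`.
#' @export
train <- function(model, x, y, x_val = NULL, y_val = NULL,
                  config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "voxcnn_model"), length(x) == length(y))
  if (!length(x)) abort("train: empty training pool")
  y <- as.numeric(y)
  ops <- model$arch$ops
  adam_m <- vector("list", length(ops))
  adam_v <- vector("list", length(ops))
  for (i in seq_along(ops)) {
    nm <- .trainable_names(ops[[i]]$kind)
    if (length(nm)) {
      adam_m[[i]] <- lapply(model$params[[i]][nm], function(p) p * 0)
      adam_v[[i]] <- adam_m[[i]]
    }
  }
  lr <- config$learning_rate
  tstep <- 0L
  best <- Inf
  wait <- 0L
  hist <- vector("list", config$epochs)

  eval_loss <- function(mdl, stacks, labels) {
    p <- predict(mdl, stacks)
    list(loss = bce(labels, p) + l2_penalty(mdl),
         acc = mean((p >= config$decision_threshold) == (labels == 1)))
  }

  with_local_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(length(x))
      batch_losses <- numeric(0)
      for (start in seq(1, length(ord), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, length(ord))]
        xb <- stack_batch(x[idx])
        yb <- y[idx]
        fw <- nn_forward(model, xb, training = TRUE)
        model <- fw$model
        if (any(!is.finite(fw$logit))) {
          abort(sprintf("training diverged: non-finite logit at epoch %d",
                        epoch))
        }
        p <- sigmoid(fw$logit)
        loss <- bce(yb, p) + l2_penalty(model)
        if (!is.finite(loss)) {
          abort(sprintf("training diverged: non-finite loss at epoch %d", epoch))
        }
        batch_losses <- c(batch_losses, loss)
        dlogit <- (p - yb) / length(yb)
        bw <- nn_backward(model, fw$caches, dlogit)
        tstep <- tstep + 1L
        for (i in seq_along(ops)) {
          gi <- bw$param_grads[[i]]
          if (is.null(gi)) next
          op <- ops[[i]]
          for (nm in names(gi)) {
            gval <- gi[[nm]]
            if (nm == "W" && op$kind %in% c("conv3d", "dense")) {
              gval <- gval + 2 * op$l2 * model$params[[i]][[nm]]
            }
            if (config$optimizer == "adam") {
              adam_m[[i]][[nm]] <- 0.9 * adam_m[[i]][[nm]] + 0.1 * gval
              adam_v[[i]][[nm]] <- 0.999 * adam_v[[i]][[nm]] + 0.001 * gval^2
              mhat <- adam_m[[i]][[nm]] / (1 - 0.9^tstep)
              vhat <- adam_v[[i]][[nm]] / (1 - 0.999^tstep)
              model$params[[i]][[nm]] <- model$params[[i]][[nm]] -
                lr * mhat / (sqrt(vhat) + 1e-8)
            } else {
              model$params[[i]][[nm]] <- model$params[[i]][[nm]] - lr * gval
            }
          }
        }
      }
      train_loss <- mean(batch_losses)
      if (!is.null(x_val) && length(x_val)) {
        ev <- eval_loss(model, x_val, y_val)
        monitored <- ev$loss
      } else {
        ev <- list(loss = NA_real_, acc = NA_real_)
        monitored <- train_loss
      }
      if (monitored < best - 1e-8) {
        best <- monitored
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$plateau_patience) {
          lr <- max(lr * config$plateau_factor, config$min_lr)
          wait <- 0L
        }
      }
      hist[[epoch]] <- tibble(epoch = epoch, lr = lr,
                              train_loss = train_loss,
                              val_loss = ev$loss, val_accuracy = ev$acc)
      if (verbose) {
        message(sprintf("epoch %3d  lr %.2e  train %.4f  val %.4f",
                        epoch, lr, train_loss, ev$loss))
      }
    }
  })
  structure(list(model = model, history = bind_rows(hist), config = config),
            class = "voxcnn_fit")
}

#' @export
print.voxcnn_fit <- function(x, ...) {
  n <- nrow(x$history)
  cat(sprintf("<voxcnn_fit  %d epochs  final train loss %.4f>\n",
              n, x$history$train_loss[n]))
  invisible(x)
}

#' @rdname tidy.voxcnn_cv
#' @export
tidy.voxcnn_fit <- function(x, ...) x$history

#' @rdname tidy.voxcnn_cv
#' @export
glance.voxcnn_fit <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  tibble(epochs = nrow(x$history), final_lr = h$lr,
         train_loss = h$train_loss, val_loss = h$val_loss,
         val_accuracy = h$val_accuracy)
}

#' @rdname autoplot.voxcnn_fit
#' @export
autoplot.voxcnn_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history,
                           c("train_loss", "val_loss"),
                           names_to = "series", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss (BCE + L2)", colour = NULL)
}
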