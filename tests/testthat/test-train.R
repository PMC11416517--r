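test_that("the learning-rate trace is non-increasing under the plateau schedule", {
  xs <- lapply(1:4, function(i) tiny_stack(200 + i,
                                           c("diseased", "control")[1 + i %% 2]))
  y <- c(1, 0, 1, 0)
  model <- build_model(tiny_arch(), seed = 1)
  fit <- train(model, xs, y, config = train_config(epochs = 12, batch_size = 2,
                                                   plateau_patience = 2,
                                                   seed = 2))
  expect_equal(nrow(fit$history), 12)
  expect_true(all(diff(fit$history$lr) <= 1e-15))
})

test_that("a reduced model memorizes two samples", {
  xs <- list(tiny_stack(301, "diseased"), tiny_stack(302, "control"))
  y <- c(1, 0)
  # no regularization for the pure memorization check
  arch <- architecture(input_shape = c(8L, 12L, 12L, 1L), filters = 4L,
                       dense_units = 8L, dropout_rate = 0, l2 = 0)
  model <- build_model(arch, seed = 3)
  fit <- train(model, xs, y,
               config = train_config(epochs = 500, batch_size = 2, seed = 4))
  final_data_loss <- bce(y, predict(fit, xs))
  expect_lt(final_data_loss, 0.01)
})

test_that("training is deterministic for identical seeds and data", {
  xs <- lapply(1:4, function(i) tiny_stack(400 + i))
  y <- c(1, 0, 1, 0)
  cfg <- train_config(epochs = 3, batch_size = 2, seed = 11)
  f1 <- train(build_model(tiny_arch(), seed = 5), xs, y, config = cfg)
  f2 <- train(build_model(tiny_arch(), seed = 5), xs, y, config = cfg)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$history, f2$history)
})

test_that("non-finite loss aborts with a diagnostic", {
  xs <- list(tiny_stack(501, "diseased"), tiny_stack(502, "control"))
  model <- build_model(tiny_arch(), seed = 6)
  # an absurd learning rate forces divergence
  expect_error(
    train(model, xs, c(1, 0),
          config = train_config(learning_rate = 1e6, optimizer = "sgd",
                                epochs = 30, batch_size = 2, seed = 7)),
    "diverged|non-finite")
})

test_that("zero-epoch training leaves the model usable", {
  xs <- list(tiny_stack(601, "diseased"), tiny_stack(602, "control"))
  model <- build_model(tiny_arch(), seed = 8)
  fit <- train(model, xs, c(1, 0), config = train_config(epochs = 0, seed = 9))
  expect_equal(nrow(fit$history), 0)
  p <- predict(fit, xs)
  expect_true(all(p > 0 & p < 1))
})

test_that("k-fold cross-validation partitions correctly and averages metrics", {
  n <- 12
  labels <- rep(c("diseased", "control"), each = n / 2)
  stacks <- lapply(seq_len(n), function(i) tiny_stack(700 + i, labels[i]))
  ids <- sprintf("P%02d", seq_len(n))
  names(stacks) <- ids
  cohort <- stack_cohort(stacks, tibble::tibble(
    sample_id = ids, patient_id = ids, label = labels,
    augmented = FALSE, source_id = ids))
  cv <- run_kfold(cohort, k = 3, augmented = TRUE, arch = tiny_arch(),
                  config = train_config(epochs = 1, batch_size = 4, seed = 1),
                  policy = augmentation_policy("rotation_affine"),
                  test_fraction = 0.2, seed = 21)
  expect_equal(nrow(cv$folds), 3)
  # mean over folds is the arithmetic mean
  expect_equal(cv$mean$accuracy, mean(cv$folds$accuracy, na.rm = TRUE))
  expect_equal(cv$mean$bce_loss, mean(cv$folds$bce_loss, na.rm = TRUE))
  # folds partition the pool
  expect_setequal(unique(cv$fold_assignment), 1:3)
  # provenance audit: no augmented copy of any patient crosses folds,
  # and no test patient appears in the training pool at all
  pool <- cv$pool_info
  for (pid in unique(pool$source_id)) {
    expect_length(unique(cv$fold_assignment[pool$source_id == pid]), 1)
  }
  expect_length(intersect(pool$source_id, cv$split$test_ids), 0)
  g <- glance(cv)
  expect_true(all(c("k", "test_accuracy") %in% names(g)))
  expect_equal(nrow(tidy(cv)), 3)
})

test_that("the unaugmented protocol holds out 10% and cross-validates the rest", {
  n <- 12
  labels <- rep(c("diseased", "control"), each = n / 2)
  stacks <- lapply(seq_len(n), function(i) tiny_stack(900 + i, labels[i]))
  ids <- sprintf("P%02d", seq_len(n))
  names(stacks) <- ids
  cohort <- stack_cohort(stacks, tibble::tibble(
    sample_id = ids, patient_id = ids, label = labels,
    augmented = FALSE, source_id = ids))
  cv <- run_kfold(cohort, k = 3, augmented = FALSE, arch = tiny_arch(),
                  config = train_config(epochs = 1, batch_size = 4, seed = 2),
                  seed = 31)
  expect_length(cv$split$test_ids, round(0.1 * 6) * 2)  # 10% per class
  expect_false(any(cv$pool_info$augmented))
  expect_equal(nrow(cv$folds), 3)
  expect_true(all(cv$folds$bce_loss >= 0))
})
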