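# Patient-level data splitting: hold out a test fraction first, then split
# the remainder into training and validation pools; optional stratification
# keeps class proportions within one patient per split.

#' Patient-level train/validation/test split
#'
#' The test set is carved first at `test_fraction`; the remaining pool is
#' then split `1 - val_fraction` / `val_fraction` into training and
#' validation. With `stratified = TRUE` the carving is done per class, so
#' proportions are preserved within rounding.
#'
#' @param patients A tibble with `patient_id` and `label` columns (e.g. a
#'   cohort manifest).
#' @param test_fraction,val_fraction Held-out fractions.
#' @param stratified Preserve class proportions per split.
#' @param seed Integer seed; the split is a pure function of its inputs.
#' @return A `split_plan` list with `train_ids`, `val_ids`, `test_ids`.
#' @export
make_split <- function(patients, test_fraction = 0.2, val_fraction = 0.2,
                       stratified = TRUE, seed = 1L) {
  stopifnot(all(c("patient_id", "label") %in% names(patients)))
  if (anyDuplicated(patients$patient_id)) {
    abort("make_split: duplicated patient ids")
  }
  if (stratified && length(unique(patients$label)) < 2 &&
      nrow(patients) > 1 && test_fraction > 0) {
    abort("make_split: stratification requires at least one patient per class")
  }
  strata <- if (stratified) split(patients$patient_id, patients$label)
            else list(all = patients$patient_id)
  test_ids <- character(0); val_ids <- character(0); train_ids <- character(0)
  with_local_seed(seed, {
    for (ids in strata) {
      ids <- sample(ids)
      n_test <- round(length(ids) * test_fraction)
      test_ids <- c(test_ids, ids[seq_len(n_test)])
      pool <- ids[setdiff(seq_along(ids), seq_len(n_test))]
      n_val <- round(length(pool) * val_fraction)
      val_ids <- c(val_ids, pool[seq_len(n_val)])
      train_ids <- c(train_ids, pool[setdiff(seq_along(pool), seq_len(n_val))])
    }
  })
  structure(list(train_ids = sort(train_ids), val_ids = sort(val_ids),
                 test_ids = sort(test_ids), stratified = stratified,
                 test_fraction = test_fraction, val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan  train=%d  val=%d  test=%d  stratified=%s>\n",
              length(x$train_ids), length(x$val_ids), length(x$test_ids),
              x$stratified))
  invisible(x)
}

# ---- stack cohorts -------------------------------------------------------

#' Assemble an in-memory stack cohort
#'
#' @param stacks Named list of `volume_stack` objects (names are sample
#'   ids).
#' @param info Tibble with one row per stack: `sample_id`, `patient_id`,
#'   `label`, `augmented` (logical), `source_id` (the originating patient).
#' @return A `stack_cohort` list.
#' @export
stack_cohort <- function(stacks, info) {
  stopifnot(identical(names(stacks), info$sample_id))
  structure(list(stacks = stacks, info = info), class = "stack_cohort")
}

#' @export
print.stack_cohort <- function(x, ...) {
  cat(sprintf("<stack_cohort  %d stacks (%d augmented)  labels: %s>\n",
              nrow(x$info), sum(x$info$augmented),
              paste(sprintf("%s=%d", names(table(x$info$label)),
                            table(x$info$label)), collapse = ", ")))
  invisible(x)
}

#' Load and preprocess a written cohort into stacks
#'
#' Prepares every patient's slices, computes normalization statistics on
#' the requested scope (training patients only, by default, to avoid
#' leaking test-set intensity statistics; `"all"` reproduces pooling over
#' the whole dataset), and builds the fixed-shape stacks.
#'
#' @param dir Cohort directory written by [write_cohort()].
#' @param split A `split_plan`; required for `stats_scope = "train_only"`.
#' @param stats_scope `"train_only"` or `"all"`.
#' @param depth,target Stack geometry (profile-dependent).
#' @param manifest Optional pre-read manifest.
#' @return A list: `cohort` (a `stack_cohort`), `stats` (`norm_stats`).
#' @export
load_cohort_stacks <- function(dir, split = NULL,
                               stats_scope = c("train_only", "all"),
                               depth = 120L, target = 128L,
                               manifest = NULL) {
  stats_scope <- match.arg(stats_scope)
  man <- manifest %||% read_manifest(dir)
  prepared <- lapply(man$patient_id, function(pid) {
    load_series(file.path(dir, pid)) |>
      prepare_slices(target = target, min_size = 128L)
  })
  names(prepared) <- man$patient_id
  stat_ids <- if (stats_scope == "train_only") {
    if (is.null(split)) abort("stats_scope='train_only' needs a split_plan")
    split$train_ids
  } else {
    man$patient_id
  }
  stats <- compute_dataset_stats(bind_rows(prepared[stat_ids]))
  stacks <- lapply(seq_along(prepared), function(i) {
    prepared[[i]] |>
      normalize_slices(stats) |>
      pad_stack(depth = depth, label = man$label[i])
  })
  names(stacks) <- man$patient_id
  info <- tibble(sample_id = man$patient_id, patient_id = man$patient_id,
                 label = man$label, augmented = FALSE,
                 source_id = man$patient_id)
  list(cohort = stack_cohort(stacks, info), stats = stats)
}

# ---- k-fold cross-validation --------------------------------------------

.subset_cohort <- function(cohort, ids) {
  keep <- cohort$info$sample_id %in% ids
  stack_cohort(cohort$stacks[cohort$info$sample_id[keep]],
               cohort$info[keep, ])
}

# deal source patients of each class round-robin into k folds
.fold_assignment <- function(info, k, group_by_patient, seed) {
  with_local_seed(seed, {
    if (group_by_patient) {
      src <- unique(info[, c("source_id", "label")])
      fold_of <- integer(0)
      for (lb in unique(src$label)) {
        ids <- sample(src$source_id[src$label == lb])
        fold_of[ids] <- rep_len(seq_len(k), length(ids))
      }
      fold_of[info$source_id]
    } else {
      fold <- integer(nrow(info))
      for (lb in unique(info$label)) {
        j <- which(info$label == lb)
        fold[sample(j)] <- rep_len(seq_len(k), length(j))
      }
      fold
    }
  })
}

#' Stratified k-fold cross-validated training and evaluation
#'
#' Reproduces the study's two evaluation protocols. Without augmentation,
#' 10% of patients are held out and k-fold (default 6) cross-validation
#' runs inside the remainder. With augmentation, 20% are held out first,
#' the training pool is class-balanced by augmented copies per `policy`,
#' and stratified k-fold (default 5) runs over the expanded pool. Test
#' metrics are computed once, from a model trained on the full pool. With
#' `group_by_patient = TRUE` (default) every augmented copy stays in the
#' same fold as its source patient, so no copy of a validation patient
#' leaks into training.
#'
#' @param cohort A `stack_cohort` of original (non-augmented) patients.
#' @param k Number of folds (>= 2).
#' @param augmented Use the augmentation protocol.
#' @param arch Architecture for the fold models.
#' @param config A [train_config()].
#' @param policy An [augmentation_policy()] (augmented protocol only).
#' @param test_fraction Held-out fraction; defaults to 0.2 with
#'   augmentation and 0.1 without.
#' @param group_by_patient Keep augmented copies with their source patient.
#' @param seed Seed for the split and fold assignment.
#' @return A `voxcnn_cv`: per-fold metrics, their mean, and held-out test
#'   metrics.
#' @export
run_kfold <- function(cohort, k = if (augmented) 5L else 6L,
                      augmented = TRUE, arch = architecture("reduced"),
                      config = train_config(),
                      policy = augmentation_policy("rotation_affine"),
                      test_fraction = if (augmented) 0.2 else 0.1,
                      group_by_patient = TRUE, seed = 1L) {
  stopifnot(inherits(cohort, "stack_cohort"), k >= 2)
  patients <- unique(cohort$info[, c("patient_id", "label")])
  split <- make_split(patients, test_fraction = test_fraction,
                      val_fraction = 0, seed = seed)
  pool <- .subset_cohort(cohort, split$train_ids)
  test <- .subset_cohort(cohort, split$test_ids)
  if (augmented) {
    pool <- balance_with_augmentation(pool, policy, seed = seed + 1L)
  }
  folds <- .fold_assignment(pool$info, k, group_by_patient, seed + 2L)
  fold_metrics <- vector("list", k)
  for (f in seq_len(k)) {
    tr_idx <- which(folds != f)
    va_idx <- which(folds == f)
    if (length(unique(pool$info$label[va_idx])) < 2 ||
        length(unique(pool$info$label[tr_idx])) < 2) {
      abort(sprintf("fold %d contains a single class; use fewer folds", f))
    }
    mdl <- build_model(arch, seed = seed + 10L + f)
    fit <- train(mdl, pool$stacks[tr_idx],
                 as.integer(pool$info$label[tr_idx] == "diseased"),
                 config = config)
    p <- predict(fit, pool$stacks[va_idx])
    fold_metrics[[f]] <- mutate(
      metric_suite(as.integer(pool$info$label[va_idx] == "diseased"), p,
                   config$decision_threshold),
      fold = f, .before = 1)
  }
  folds_tbl <- bind_rows(fold_metrics)
  mean_tbl <- summarise(folds_tbl, across(
    all_of(c("accuracy", "auc", "precision", "recall", "bce_loss")),
    function(v) mean(v, na.rm = TRUE)))
  final <- build_model(arch, seed = seed + 99L)
  final_fit <- train(final, pool$stacks,
                     as.integer(pool$info$label == "diseased"),
                     config = config)
  test_metrics <- metric_suite(
    as.integer(test$info$label == "diseased"),
    predict(final_fit, test$stacks), config$decision_threshold)
  structure(list(k = k, augmented = augmented, folds = folds_tbl,
                 mean = mean_tbl, test = test_metrics, split = split,
                 fold_assignment = folds, pool_info = pool$info,
                 fit = final_fit),
            class = "voxcnn_cv")
}

#' @export
print.voxcnn_cv <- function(x, ...) {
  cat(sprintf("<voxcnn_cv  k=%d  augmented=%s>\nmean over folds:\n",
              x$k, x$augmented))
  print(as.data.frame(x$mean), row.names = FALSE)
  cat("held-out test:\n")
  print(as.data.frame(x$test[, 1:5]), row.names = FALSE)
  invisible(x)
}

#' Tidiers for fitted objects
#'
#' `tidy()` returns per-unit rows (folds, epochs, or layers);
#' `glance()` returns a one-row summary.
#'
#' @param x A `voxcnn_cv`, `voxcnn_fit` or `voxcnn_architecture`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.voxcnn_cv <- function(x, ...) x$folds

#' @rdname tidy.voxcnn_cv
#' @export
glance.voxcnn_cv <- function(x, ...) {
  mutate(x$mean, k = x$k, augmented = x$augmented,
         test_accuracy = x$test$accuracy, test_auc = x$test$auc)
}

#' Plot methods for fitted objects
#'
#' @param object Fitted object.
#' @param ... Unused.
#' @return A ggplot.
#' @rdname autoplot.voxcnn_fit
#' @export
autoplot.voxcnn_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$folds,
                              c("accuracy", "auc", "precision", "recall"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$fold), y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "fold", y = NULL)
}
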