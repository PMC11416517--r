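# One-call orchestration: phantom cohort -> DICOM preprocessing -> split ->
# augmentation -> training -> held-out evaluation -> Grad-CAM overlays,
# with every seed recorded and all artifacts addressable from a run
# manifest.

#' Stack geometry and phantom defaults for a profile
#'
#' The `"paper"` profile is the full `(120, 128, 128, 1)` stack with the
#' study's cohort shape (axial totals 23--115, matrix sizes 64/256/512).
#' The `"reduced"` profile is a `(24, 32, 32, 1)` desk-scale variant with
#' proportionally smaller slice counts and stronger, larger lesions, used
#' for tractable training runs and tests.
#'
#' @param profile `"paper"` or `"reduced"`.
#' @return A list: `depth`, `target`, `slice_count_range`, `matrix_sizes`,
#'   `lesion_radius_vox`, `lesion_contrast`.
#' @export
profile_spec <- function(profile = c("paper", "reduced")) {
  profile <- match.arg(profile)
  if (profile == "paper") {
    list(depth = 120L, target = 128L, slice_count_range = c(23L, 115L),
         matrix_sizes = c(64L, 256L, 512L), lesion_radius_vox = 7,
         lesion_contrast = 1.8, lesion_depth_frac = 0.10)
  } else {
    list(depth = 24L, target = 32L, slice_count_range = c(9L, 21L),
         matrix_sizes = c(64L, 256L), lesion_radius_vox = 14,
         lesion_contrast = 3, lesion_depth_frac = 0.25)
  }
}

#' Pipeline run configuration
#'
#' @param profile `"reduced"` (desk scale, default) or `"paper"` (full
#'   stack geometry); fixes the input shape consistently across all stages.
#' @param n_diseased,n_control Phantom cohort composition.
#' @param lesion_contrast Override the profile's lesion contrast.
#' @param stats_scope Normalization statistics scope (see
#'   [load_cohort_stacks()]).
#' @param test_fraction,val_fraction Split fractions.
#' @param augmentation Policy preset name, or `"none"`.
#' @param epochs,batch_size,learning_rate,optimizer Training parameters.
#' @param output_dir Where artifacts are written.
#' @param seed Global seed; all stage seeds derive from it.
#' @return A `run_config` list.
#' @export
run_config <- function(profile = c("reduced", "paper"), n_diseased = 27L,
                       n_control = 13L, lesion_contrast = NULL,
                       stats_scope = "train_only", test_fraction = 0.2,
                       val_fraction = 0.2,
                       augmentation = "rotation_affine", epochs = 30L,
                       batch_size = 4L, learning_rate = 0.001,
                       optimizer = "adam",
                       output_dir = tempfile("voxcnn_run"), seed = 1L) {
  profile <- match.arg(profile)
  ps <- profile_spec(profile)
  if (!is.null(lesion_contrast)) ps$lesion_contrast <- lesion_contrast
  structure(list(profile = profile, spec = ps,
                 n_diseased = as.integer(n_diseased),
                 n_control = as.integer(n_control),
                 stats_scope = stats_scope, test_fraction = test_fraction,
                 val_fraction = val_fraction, augmentation = augmentation,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Generates (or reuses) the phantom DICOM cohort, preprocesses every
#' patient into fixed-shape stacks, splits at patient level, balances the
#' training pool by augmentation, trains the classifier, evaluates once on
#' the held-out test set, and writes Grad-CAM overlays for example test
#' patients. Re-running with the same configuration reproduces all metrics.
#'
#' @param config A [run_config()].
#' @param verbose Print stage progress.
#' @return A `voxcnn_run` report: `$metrics` (held-out test
#'   `metrics_report`), `$fit`, `$split`, `$paths`, `$config`.
#' @export
run_pipeline <- function(config = run_config(), verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  ps <- config$spec

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  say("stage 1/6: phantom cohort")
  pcfg <- phantom_config(
    n_diseased = config$n_diseased, n_control = config$n_control,
    slice_count_range = ps$slice_count_range,
    matrix_sizes = ps$matrix_sizes,
    lesion_radius_vox = ps$lesion_radius_vox,
    lesion_contrast = ps$lesion_contrast,
    lesion_depth_frac = ps$lesion_depth_frac,
    seed = config$seed)
  cohort_dir <- file.path(out, "cohort")
  manifest <- stage("phantom", write_cohort(pcfg, cohort_dir))

  say("stage 2/6: split")
  split <- stage("split", make_split(manifest,
                                     test_fraction = config$test_fraction,
                                     val_fraction = config$val_fraction,
                                     seed = config$seed + 1L))

  say("stage 3/6: preprocessing")
  loaded <- stage("preprocess", load_cohort_stacks(
    cohort_dir, split = split, stats_scope = config$stats_scope,
    depth = ps$depth, target = ps$target, manifest = manifest))
  cohort <- loaded$cohort
  saveRDS(cohort$stacks, file.path(out, "stacks.rds"))

  say("stage 4/6: augmentation")
  train_pool <- .subset_cohort(cohort, split$train_ids)
  if (!identical(config$augmentation, "none")) {
    pol <- augmentation_policy(config$augmentation)
    train_pool <- stage("augment",
                        balance_with_augmentation(train_pool, pol,
                                                  seed = config$seed + 2L))
  }

  say("stage 5/6: training (%d epochs)", config$epochs)
  arch <- architecture(if (config$profile == "paper") "paper" else "reduced")
  model <- build_model(arch, seed = config$seed + 3L)
  tcfg <- train_config(optimizer = config$optimizer,
                       learning_rate = config$learning_rate,
                       batch_size = config$batch_size,
                       epochs = config$epochs, seed = config$seed + 4L)
  val_pool <- .subset_cohort(cohort, split$val_ids)
  fit <- stage("train", train(
    model, train_pool$stacks,
    as.integer(train_pool$info$label == "diseased"),
    x_val = if (length(val_pool$stacks)) val_pool$stacks else NULL,
    y_val = as.integer(val_pool$info$label == "diseased"),
    config = tcfg, verbose = verbose))
  saveRDS(fit$model, file.path(out, "model.rds"))
  utils::write.table(fit$history, file.path(out, "history.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  say("stage 6/6: evaluation + explanation")
  test_pool <- .subset_cohort(cohort, split$test_ids)
  metrics <- stage("evaluate", metric_suite(
    as.integer(test_pool$info$label == "diseased"),
    predict(fit, test_pool$stacks)))
  utils::write.table(metrics, file.path(out, "metrics.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cam_paths <- character(0)
  for (lb in intersect(c("diseased", "control"), test_pool$info$label)) {
    pid <- test_pool$info$patient_id[test_pool$info$label == lb][1]
    cam <- stage("explain", grad_cam(fit, test_pool$stacks[[pid]]))
    cam_paths <- c(cam_paths, render_overlays(
      cam, test_pool$stacks[[pid]],
      file.path(out, "overlays", paste0(lb, "_", pid))))
  }

  paths <- list(cohort = cohort_dir,
                stacks = file.path(out, "stacks.rds"),
                model = file.path(out, "model.rds"),
                history = file.path(out, "history.tsv"),
                metrics = file.path(out, "metrics.tsv"),
                overlays = cam_paths)
  seeds <- list(global = config$seed, phantom = config$seed,
                split = config$seed + 1L, augment = config$seed + 2L,
                init = config$seed + 3L, train = config$seed + 4L)
  run_manifest <- tibble(
    artifact = c(names(paths)[1:5], rep("overlay", length(cam_paths))),
    path = c(unlist(paths[1:5], use.names = FALSE), cam_paths))
  utils::write.table(run_manifest, file.path(out, "run_manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  structure(list(metrics = metrics, fit = fit, split = split,
                 manifest = manifest, paths = paths, seeds = seeds,
                 config = config),
            class = "voxcnn_run")
}

#' @export
print.voxcnn_run <- function(x, ...) {
  cat(sprintf("<voxcnn_run  profile=%s  seed=%d>\nheld-out test metrics:\n",
              x$config$profile, x$config$seed))
  print(as.data.frame(x$metrics[, 1:5]), row.names = FALSE)
  invisible(x)
}
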