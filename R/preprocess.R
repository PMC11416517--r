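# DICOM series -> fixed-shape normalized 3D stack.
# Stages: load -> sort by instance number -> (group sequences) -> keep axial
# T1W/T2W/FLAIR -> discard small matrices -> area-downsample to the target
# grid -> z-score normalize with cohort statistics -> zero-pad the depth axis.

#' Load a patient's DICOM directory into a slice tibble
#'
#' Reads every file in `dir` as DICOM; unreadable or corrupt files are
#' skipped with a warning. Pixel data is passed through untransformed.
#'
#' @param dir Directory containing one patient's DICOM files.
#' @return A slice tibble (`patient_id`, `instance_number`, `plane`,
#'   `sequence`, `rows`, `cols`, `pixels` list-column).
#' @export
load_series <- function(dir) {
  if (!dir.exists(dir)) abort(sprintf("no such directory: '%s'", dir))
  files <- sort(list.files(dir, full.names = TRUE))
  files <- files[!dir.exists(files) & !grepl("manifest", basename(files))]
  if (!length(files)) abort(sprintf("no files in '%s'", dir))
  recs <- list()
  for (f in files) {
    rec <- tryCatch(dcm_read(f), error = function(e) {
      warn(sprintf("skipping unreadable DICOM '%s': %s",
                   basename(f), conditionMessage(e)))
      NULL
    })
    if (!is.null(rec)) recs[[length(recs) + 1L]] <- rec
  }
  if (!length(recs)) abort(sprintf("no readable DICOM files in '%s'", dir))
  tibble(
    patient_id = map_chr(recs, "patient_id"),
    instance_number = map_int(recs, "instance_number"),
    plane = map_chr(recs, "plane"),
    sequence = map_chr(recs, "sequence"),
    rows = map_int(recs, "rows"),
    cols = map_int(recs, "cols"),
    pixels = map(recs, "pixels")
  )
}

#' Sort slices by acquisition instance number
#'
#' Stable ascending sort on `instance_number`; the incoming row order is
#' otherwise irrelevant, so any permutation of the same slices yields the
#' same output.
#'
#' @param slices A slice tibble.
#' @return The sorted slice tibble.
#' @export
sort_by_instance <- function(slices) {
  if (anyNA(slices$instance_number)) {
    bad <- which(is.na(slices$instance_number))
    abort(sprintf("missing instance_number on slice row(s) %s",
                  paste(bad, collapse = ", ")))
  }
  arrange(slices, .data$instance_number)
}

#' Keep only axial T1W/T2W/FLAIR slices
#'
#' Retains exactly the slices the model consumes; relative order and pixel
#' values are untouched.
#'
#' @param slices A slice tibble.
#' @return The filtered slice tibble; errors if nothing remains.
#' @export
filter_axial_sequences <- function(slices) {
  out <- filter(slices, .data$plane == "axial",
                .data$sequence %in% c("T1W", "T2W", "FLAIR"))
  if (!nrow(out)) {
    abort("no axial T1W/T2W/FLAIR slices remain; patient unusable")
  }
  out
}

#' Discard small-matrix (scout) slices
#'
#' Removes slices whose square matrix is smaller than `min_size` pixels
#' (scout/localizer images carry no diagnostic content).
#'
#' @param slices A slice tibble.
#' @param min_size Minimum matrix edge retained.
#' @return The filtered slice tibble (possibly empty).
#' @export
discard_small <- function(slices, min_size = 128L) {
  filter(slices, .data$rows >= min_size)
}

#' Area-preserving downsample of a square slice
#'
#' Each target pixel is the exact area-weighted mean of the source pixels it
#' covers (anti-aliased local-mean shrink). Equal sizes return the input
#' unchanged; upscaling is refused.
#'
#' @param pixels Square numeric matrix.
#' @param target Target edge length.
#' @return `target` x `target` numeric matrix.
#' @export
area_resample <- function(pixels, target = 128L) {
  n <- nrow(pixels)
  stopifnot(is.matrix(pixels), n == ncol(pixels))
  if (n == target) return(pixels)
  if (n < target) {
    abort(sprintf("area_resample: upscaling %d -> %d is not defined", n, target))
  }
  W <- .area_weights(n, target)
  W %*% pixels %*% t(W)
}

# target x source row-stochastic matrix of interval-overlap fractions
.area_weights <- function(n, target) {
  ratio <- n / target
  W <- matrix(0, target, n)
  for (t in seq_len(target)) {
    lo <- (t - 1) * ratio
    hi <- t * ratio
    j0 <- floor(lo) + 1
    j1 <- ceiling(hi)
    for (j in j0:j1) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) W[t, j] <- ov / ratio
    }
  }
  W
}

#' Resize every slice of a series to the model grid
#'
#' @param slices A slice tibble (square matrices, edge >= `target`).
#' @param target Target edge length.
#' @return The slice tibble with resized `pixels` and updated `rows`/`cols`.
#' @export
resize_slices <- function(slices, target = 128L) {
  mutate(slices,
         pixels = map(.data$pixels, area_resample, target = target),
         rows = as.integer(target), cols = as.integer(target))
}

#' Pooled intensity statistics of a slice collection
#'
#' Mean and population standard deviation over every pixel of every slice;
#' used as the z-score reference for the whole dataset.
#'
#' @param slices A slice tibble (normally all slices of the training
#'   patients, after filtering/resizing).
#' @return A `norm_stats` list with elements `mean` and `sd`.
#' @export
compute_dataset_stats <- function(slices) {
  n <- 0; s <- 0; ss <- 0
  for (px in slices$pixels) {
    n <- n + length(px)
    s <- s + sum(px)
    ss <- ss + sum(as.numeric(px)^2)
  }
  if (n < 2) abort("compute_dataset_stats: need at least 2 pixels")
  mu <- s / n
  v <- ss / n - mu^2
  if (v <= 0) abort("compute_dataset_stats: constant cohort, sd == 0")
  structure(list(mean = mu, sd = sqrt(v)), class = "norm_stats")
}

#' Z-score normalize slices with fixed cohort statistics
#'
#' Every pixel x becomes (x - mean) / sd.
#'
#' @param slices A slice tibble.
#' @param stats A `norm_stats` object from [compute_dataset_stats()].
#' @return The slice tibble with normalized (double) pixel matrices.
#' @export
normalize_slices <- function(slices, stats) {
  stopifnot(inherits(stats, "norm_stats"), stats$sd > 0)
  mutate(slices, pixels = map(.data$pixels,
                              function(p) (p - stats$mean) / stats$sd))
}

#' Zero-pad an ordered slice series into a fixed-shape volume stack
#'
#' Real slices occupy the leading depth indices; the remainder of the depth
#' axis is exactly zero (which, after z-score normalization, is the cohort
#' mean intensity). A series longer than `depth` is refused -- there is no
#' defined truncation policy.
#'
#' @param slices A slice tibble of 1..`depth` equally sized square slices in
#'   final order.
#' @param depth Stack depth.
#' @param label Optional class label stored on the stack.
#' @return A `volume_stack`: array of dim `c(depth, size, size, 1)` with
#'   attributes `patient_id`, `label`, `n_real_slices`.
#' @export
pad_stack <- function(slices, depth = 120L, label = NA_character_) {
  n <- nrow(slices)
  if (n < 1) abort("pad_stack: empty slice series")
  if (n > depth) {
    abort(sprintf(paste("pad_stack: %d slices exceed stack depth %d;",
                        "no truncation policy is defined"), n, depth))
  }
  size <- nrow(slices$pixels[[1]])
  for (p in slices$pixels) {
    if (nrow(p) != size || ncol(p) != size) {
      abort("pad_stack: slices must all be square and equally sized")
    }
  }
  vox <- array(0, c(depth, size, size, 1L))
  for (i in seq_len(n)) vox[i, , , 1L] <- slices$pixels[[i]]
  new_volume_stack(vox, patient_id = slices$patient_id[1] %||% NA_character_,
                   label = label, n_real_slices = n)
}

new_volume_stack <- function(vox, patient_id, label, n_real_slices) {
  structure(vox, patient_id = patient_id, label = label,
            n_real_slices = as.integer(n_real_slices),
            class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<volume_stack %s  patient=%s  label=%s  real slices=%d>\n",
              paste(d, collapse = "x"), attr(x, "patient_id"),
              attr(x, "label"), attr(x, "n_real_slices")))
  invisible(x)
}

#' Build the fixed-shape normalized stack for one patient directory
#'
#' Composition of the full preprocessing chain: load, sort by instance
#' number, group sequences (stable T1W < T2W < FLAIR order), keep axial
#' diagnostic sequences, discard scout matrices, area-downsample, z-score
#' normalize, zero-pad. The result has shape
#' `(depth, target, target, 1)` for every admissible input and is invariant
#' to the on-disk file order.
#'
#' @param dir Patient DICOM directory.
#' @param stats `norm_stats` (normally from the training portion; see
#'   [compute_dataset_stats()]).
#' @param depth,target Stack depth and in-plane size: `120`/`128` for the
#'   full profile, `24`/`32` for the reduced profile.
#' @param min_size Scout-discard threshold.
#' @param label Optional class label to attach.
#' @return A `volume_stack`.
#' @export
build_stack <- function(dir, stats, depth = 120L, target = 128L,
                        min_size = 128L, label = NA_character_) {
  load_series(dir) |>
    prepare_slices(target = target, min_size = min_size) |>
    normalize_slices(stats) |>
    pad_stack(depth = depth, label = label)
}

#' Deterministic slice selection/ordering/resizing (no normalization)
#'
#' The shared front half of [build_stack()], exposed so that dataset
#' statistics can be computed on exactly the slices that enter the stacks.
#'
#' @inheritParams build_stack
#' @param slices A slice tibble (e.g. from [load_series()]).
#' @return A slice tibble, ordered and resized.
#' @export
prepare_slices <- function(slices, target = 128L, min_size = 128L) {
  slices |>
    sort_by_instance() |>
    arrange(match(.data$sequence, c("T1W", "T2W", "FLAIR"))) |>
    filter_axial_sequences() |>
    discard_small(min_size = min_size) |>
    resize_slices(target = target)
}

#' @importFrom rlang .data
NULL
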