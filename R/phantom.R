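# Synthetic MRI phantom cohort: seeded, on-disk DICOM series that mimic the
# structure of a small clinical cSVD cohort -- per-patient axial T1W/T2W/FLAIR
# series with widely varying slice counts, mixed matrix sizes (small scout
# images plus 256/512 diagnostic slices), extra sagittal/coronal series, and,
# in the diseased class, hyperintense periventricular ellipsoidal lesions on
# T2W/FLAIR axial slices (the imaging biomarker of white matter
# hyperintensities).

#' Phantom cohort configuration
#'
#' Defines a seeded synthetic cohort. Defaults mirror the study conditions:
#' 30 diseased vs 15 control patients, per-patient filtered axial slice
#' totals in \[23, 115\], matrix sizes 64/256/512 (the 64 x 64 images are
#' scout slices that preprocessing discards), and T1W/T2W/FLAIR sequences.
#'
#' @param n_diseased,n_control Patients per class (non-negative, at least one
#'   patient overall).
#' @param slice_count_range Closed integer interval for the per-patient
#'   total number of qualifying axial slices (shared across the enabled
#'   sequences).
#' @param matrix_sizes Square pixel matrix sizes present in the cohort;
#'   sizes below 128 are emitted as scout slices.
#' @param sequences Sequence tags to emit (subset of T1W/T2W/FLAIR).
#' @param planes Planes to emit; non-axial planes carry structural content
#'   only and are filtered out downstream.
#' @param lesion_count Lesions per diseased volume.
#' @param lesion_radius_vox In-plane lesion radius, in voxels of a 128-pixel
#'   reference grid (so the normalized radius is `lesion_radius_vox / 128`).
#' @param lesion_contrast Multiplicative hyperintensity of lesions over the
#'   surrounding white matter (> 0; values > 1 make lesions bright).
#' @param lesion_depth_frac Lesion depth radius as a fraction of a sequence
#'   block's depth. Chosen so a lesion spans on the order of one slice
#'   spacing: 0.10 suits the full profile's ~12 axial slices per sequence;
#'   profiles with coarser depth sampling scale it up to keep the same
#'   relative extent (see [profile_spec()]).
#' @param noise_sigma Gaussian pixel noise standard deviation (intensity
#'   units on the 0--4095 scale).
#' @param seed Integer seed; the whole cohort is a pure function of this
#'   configuration.
#' @return A `phantom_config` object (a validated list).
#' @examples
#' cfg <- phantom_config(n_diseased = 2, n_control = 1, seed = 7)
#' @export
phantom_config <- function(n_diseased = 30, n_control = 15,
                           slice_count_range = c(23L, 115L),
                           matrix_sizes = c(64L, 256L, 512L),
                           sequences = c("T1W", "T2W", "FLAIR"),
                           planes = c("axial", "sagittal", "coronal"),
                           lesion_count = 4L,
                           lesion_radius_vox = 7,
                           lesion_contrast = 1.8,
                           lesion_depth_frac = 0.10,
                           noise_sigma = 20,
                           seed = 1L) {
  if (n_diseased < 0 || n_control < 0 || n_diseased + n_control < 1) {
    abort("phantom_config: need n_diseased >= 0, n_control >= 0, total >= 1")
  }
  if (length(slice_count_range) != 2 || slice_count_range[1] < 1 ||
      slice_count_range[2] < slice_count_range[1]) {
    abort("phantom_config: slice_count_range must be a valid interval with lower bound >= 1")
  }
  if (length(sequences) < 1 || !all(sequences %in% c("T1W", "T2W", "FLAIR"))) {
    abort("phantom_config: sequences must be a non-empty subset of T1W/T2W/FLAIR")
  }
  if (length(planes) < 1 ||
      !all(planes %in% c("axial", "sagittal", "coronal"))) {
    abort("phantom_config: planes must be a non-empty subset of axial/sagittal/coronal")
  }
  if (lesion_contrast <= 0) abort("phantom_config: lesion_contrast must be > 0")
  if (!length(matrix_sizes) || any(matrix_sizes < 8)) {
    abort("phantom_config: matrix_sizes must be sizes >= 8")
  }
  structure(
    list(
      n_diseased = as.integer(n_diseased), n_control = as.integer(n_control),
      slice_count_range = as.integer(slice_count_range),
      matrix_sizes = sort(as.integer(matrix_sizes)),
      sequences = sequences, planes = planes,
      lesion_count = as.integer(lesion_count),
      lesion_radius_vox = lesion_radius_vox,
      lesion_contrast = lesion_contrast,
      lesion_depth_frac = lesion_depth_frac,
      noise_sigma = noise_sigma,
      seed = as.integer(seed)
    ),
    class = "phantom_config"
  )
}

# run code under a local seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# per-sequence stylized intensity profile (tissue, CSF/ventricle) on the
# 0-4095 scale; only relative contrasts matter downstream
.seq_profile <- list(
  T1W   = c(tissue = 650, csf = 160),
  T2W   = c(tissue = 400, csf = 900),
  FLAIR = c(tissue = 430, csf = 130)
)

# Structural geometry of one patient, drawn with a fixed number of RNG calls
# so that image synthesis and mask reconstruction agree exactly.
patient_geometry <- function(config, label, seed) {
  with_local_seed(seed, {
    rng <- config$slice_count_range
    n_total <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1)
    nseq <- length(config$sequences)
    base <- n_total %/% nseq
    counts <- rep(base, nseq)
    extra <- n_total - base * nseq
    if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
    names(counts) <- config$sequences
    big_sizes <- config$matrix_sizes[config$matrix_sizes >= 128]
    if (!length(big_sizes)) abort("phantom: no matrix size >= 128 configured")
    seq_size <- setNames(
      big_sizes[sample.int(length(big_sizes), nseq, replace = TRUE)],
      config$sequences
    )
    nles <- config$lesion_count
    lesions <- NULL
    if (label == "diseased" && nles > 0) {
      # periventricular caps are bilateral: alternate sides deterministically,
      # jitter everything else
      lesions <- tibble(
        u = 0.5 + runif(nles, -0.14, 0.14),
        v = 0.5 + rep_len(c(-1, 1), nles) *
          (0.16 + runif(nles, 0, 0.07)),
        cz = runif(nles, 0.42, 0.58),
        r = (config$lesion_radius_vox / 128) * runif(nles, 0.85, 1.15),
        rz = config$lesion_depth_frac %||% 0.10
      )
    }
    list(total_axial = n_total, counts = counts, seq_size = seq_size,
         lesions = lesions, label = label)
  })
}

.ellipse_mask <- function(n, cu, cv, ru, rv) {
  u <- (seq_len(n) - 0.5) / n
  v <- (seq_len(n) - 0.5) / n
  du <- outer((u - cu) / ru, rep(1, n))
  dv <- outer(rep(1, n), (v - cv) / rv)
  du^2 + dv^2 <= 1
}

# lesion mask (logical) for a qualifying axial slice at depth fraction z
.lesion_slice_mask <- function(n, geom, sequence, z) {
  m <- matrix(FALSE, n, n)
  if (is.null(geom$lesions) || !sequence %in% c("T2W", "FLAIR")) return(m)
  for (i in seq_len(nrow(geom$lesions))) {
    L <- geom$lesions[i, ]
    dz <- (z - L$cz) / L$rz
    if (abs(dz) >= 1) next
    s <- sqrt(1 - dz^2)
    m <- m | .ellipse_mask(n, L$u, L$v, L$r * s, 0.8 * L$r * s)
  }
  m
}

# Noise-free anatomy for one slice; z in [0,1] is the depth fraction.
.slice_signal <- function(n, geom, sequence, plane, z) {
  prof <- .seq_profile[[sequence]] %||% c(tissue = 500, csf = 300)
  img <- matrix(0, n, n)
  head_scale <- sqrt(pmax(0.1, 1 - ((z - 0.5) / 0.58)^2))
  head <- .ellipse_mask(n, 0.5, 0.5, 0.40 * head_scale, 0.34 * head_scale)
  img[head] <- prof[["tissue"]]
  if (plane == "axial") {
    if (z > 0.33 && z < 0.68) {
      vent <- .ellipse_mask(n, 0.5, 0.40, 0.13, 0.05) |
        .ellipse_mask(n, 0.5, 0.60, 0.13, 0.05)
      img[vent & head] <- prof[["csf"]]
    }
    les <- .lesion_slice_mask(n, geom, sequence, z)
    img[les & head] <- prof[["tissue"]] * (geom$lesion_contrast %||% 1)
  }
  img
}

.finish_slice <- function(signal, noise_sigma) {
  n <- nrow(signal)
  img <- signal + matrix(rnorm(n * n, 0, noise_sigma), n, n)
  matrix(as.integer(pmin(4095, pmax(0, round(img)))), n, n)
}

#' Generate one patient's DICOM slice series in memory
#'
#' Emits a multi-plane, multi-sequence slice series as a slice tibble
#' (one row per slice, pixel matrices in the `pixels` list-column).
#' Diseased patients carry hyperintense periventricular ellipsoidal lesions
#' near mid-depth on axial T2W/FLAIR slices; controls carry the same
#' brain-mimicking background without lesions. Output is byte-identical for
#' identical arguments.
#'
#' Emission order is fixed: axial slices first (sequences in the order given
#' by `config$sequences`, scouts before diagnostic slices), then sagittal,
#' then coronal.
#'
#' @param config A [phantom_config()].
#' @param patient_id Identifier string.
#' @param label `"diseased"` or `"control"`.
#' @param seed Integer seed for this patient.
#' @return A slice tibble with columns `patient_id`, `instance_number`,
#'   `plane`, `sequence`, `rows`, `cols`, `pixels`.
#' @export
generate_patient_series <- function(config, patient_id, label, seed) {
  stopifnot(inherits(config, "phantom_config"))
  if (!label %in% c("diseased", "control")) {
    abort(sprintf("label must be 'diseased' or 'control', got '%s'", label))
  }
  geom <- patient_geometry(config, label, seed)
  geom$lesion_contrast <- config$lesion_contrast
  scout_sizes <- config$matrix_sizes[config$matrix_sizes < 128]
  n_scout <- if (length(scout_sizes)) 2L else 0L

  with_local_seed(seed + 1L, {
    rows_out <- list()
    if ("axial" %in% config$planes) {
      for (sq in config$sequences) {
        n_ax <- geom$counts[[sq]]
        inst <- 0L
        if (n_scout > 0) {
          for (k in seq_len(n_scout)) {
            inst <- inst + 1L
            sz <- min(scout_sizes)
            sig <- .slice_signal(sz, geom, sq, "axial", z = 0.05 * k)
            rows_out[[length(rows_out) + 1L]] <- list(
              patient_id = patient_id, instance_number = inst,
              plane = "axial", sequence = sq, rows = sz, cols = sz,
              pixels = .finish_slice(sig, config$noise_sigma)
            )
          }
        }
        sz <- geom$seq_size[[sq]]
        for (k in seq_len(n_ax)) {
          inst <- inst + 1L
          z <- (k - 0.5) / n_ax
          sig <- .slice_signal(sz, geom, sq, "axial", z)
          rows_out[[length(rows_out) + 1L]] <- list(
            patient_id = patient_id, instance_number = inst,
            plane = "axial", sequence = sq, rows = sz, cols = sz,
            pixels = .finish_slice(sig, config$noise_sigma)
          )
        }
      }
    }
    for (pl in intersect(c("sagittal", "coronal"), config$planes)) {
      sq <- config$sequences[1]
      sz <- geom$seq_size[[sq]]
      for (k in 1:3) {
        sig <- .slice_signal(sz, geom, sq, pl, z = k / 4)
        rows_out[[length(rows_out) + 1L]] <- list(
          patient_id = patient_id, instance_number = k,
          plane = pl, sequence = sq, rows = sz, cols = sz,
          pixels = .finish_slice(sig, config$noise_sigma)
        )
      }
    }
    tibble(
      patient_id = map_chr(rows_out, "patient_id"),
      instance_number = map_int(rows_out, "instance_number"),
      plane = map_chr(rows_out, "plane"),
      sequence = map_chr(rows_out, "sequence"),
      rows = map_int(rows_out, function(r) as.integer(r$rows)),
      cols = map_int(rows_out, function(r) as.integer(r$cols)),
      pixels = map(rows_out, "pixels")
    )
  })
}

#' Ground-truth lesion mask in preprocessed stack space
#'
#' Reconstructs, from the patient's seed alone, the binary lesion mask
#' aligned to the volume produced by [build_stack()] (sequence-major slice
#' order, resized in-plane grid, zero-padded tail). Controls yield an
#' all-`FALSE` mask.
#'
#' @inheritParams generate_patient_series
#' @param depth,target Stack depth and in-plane size (match the profile used
#'   for preprocessing).
#' @return Logical array of dim `c(depth, target, target)`.
#' @export
stack_lesion_mask <- function(config, patient_id, label, seed,
                              depth = 120L, target = 128L) {
  geom <- patient_geometry(config, label, seed)
  mask <- array(FALSE, c(depth, target, target))
  i <- 0L
  for (sq in config$sequences) {
    n_ax <- geom$counts[[sq]]
    for (k in seq_len(n_ax)) {
      i <- i + 1L
      z <- (k - 0.5) / n_ax
      mask[i, , ] <- .lesion_slice_mask(target, geom, sq, z)
    }
  }
  mask
}

.patient_seed <- function(config, i) {
  as.integer((as.double(config$seed) * 10007 + i * 101) %% 2147483629)
}

#' Write a synthetic DICOM cohort to disk
#'
#' Creates one subdirectory per patient containing one DICOM file per slice,
#' plus a tab-delimited `manifest.tsv` mapping patient id to class label
#' (with the per-patient seed and qualifying-axial-slice count as
#' bookkeeping columns).
#'
#' @param config A [phantom_config()].
#' @param out_dir Output directory (created if missing).
#' @return The cohort manifest as a tibble, invisibly classed
#'   `cohort_manifest`.
#' @examples
#' \donttest{
#' cfg <- phantom_config(n_diseased = 1, n_control = 1,
#'                       slice_count_range = c(9, 12), seed = 3)
#' man <- write_cohort(cfg, file.path(tempdir(), "cohort"))
#' }
#' @export
write_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "phantom_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0) {
    abort(sprintf("write_cohort: cannot write to '%s'", out_dir))
  }
  labels <- c(rep("diseased", config$n_diseased),
              rep("control", config$n_control))
  rows <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    pid <- sprintf("P%03d", i)
    pseed <- .patient_seed(config, i)
    series <- generate_patient_series(config, pid, labels[i], pseed)
    pdir <- file.path(out_dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    for (j in seq_len(nrow(series))) {
      f <- file.path(pdir, sprintf("%s_%s_%03d.dcm", series$sequence[j],
                                   series$plane[j], series$instance_number[j]))
      dcm_write(f, series$pixels[[j]], pid, series$instance_number[j],
                series$plane[j], series$sequence[j])
    }
    n_axial <- sum(series$plane == "axial" & series$rows >= 128 &
                     series$sequence %in% c("T1W", "T2W", "FLAIR"))
    rows[[i]] <- tibble(patient_id = pid, label = labels[i],
                        patient_seed = pseed, n_axial = n_axial)
  }
  manifest <- bind_rows(rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  class(manifest) <- c("cohort_manifest", class(manifest))
  invisible(manifest)
}

#' Read a cohort manifest written by [write_cohort()]
#'
#' @param dir Cohort directory containing `manifest.tsv`.
#' @return The manifest tibble.
#' @export
read_manifest <- function(dir) {
  f <- file.path(dir, "manifest.tsv")
  if (!file.exists(f)) abort(sprintf("no manifest.tsv in '%s'", dir))
  man <- tibble::as_tibble(utils::read.delim(f, stringsAsFactors = FALSE))
  class(man) <- c("cohort_manifest", class(man))
  man
}

#' @importFrom purrr map_chr
NULL
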