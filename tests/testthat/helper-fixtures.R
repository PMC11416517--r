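# Shared fixtures, generated in code at test time.

# small phantom configuration: fast to synthesize, still multi-sequence,
# multi-plane, mixed matrix sizes
tiny_phantom_config <- function(n_diseased = 1, n_control = 1, seed = 7,
                                lesion_contrast = 2.5, ...) {
  phantom_config(n_diseased = n_diseased, n_control = n_control,
                 slice_count_range = c(9L, 12L),
                 matrix_sizes = c(64L, 256L),
                 lesion_radius_vox = 14, lesion_contrast = lesion_contrast,
                 seed = seed, ...)
}

# a written tiny cohort, cached for the whole test run
tiny_cohort_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "voxcnn-tiny-cohort")
      if (!file.exists(file.path(dir, "manifest.tsv"))) {
        write_cohort(tiny_phantom_config(n_diseased = 2, n_control = 1,
                                         seed = 71), dir)
      }
    }
    dir
  }
})

# arbitrary normalization stats for stack-building tests
fixed_stats <- function(mean = 300, sd = 200) {
  structure(list(mean = mean, sd = sd), class = "norm_stats")
}

# random normalized volume stack of the reduced-profile shape
random_stack <- function(seed, n_real = 12L, depth = 24L, size = 32L,
                         label = "diseased") {
  withr::with_seed(seed, {
    a <- array(0, c(depth, size, size, 1))
    a[seq_len(n_real), , , 1] <- rnorm(n_real * size * size)
    voxcnn:::new_volume_stack(a, patient_id = paste0("R", seed),
                              label = label, n_real_slices = n_real)
  })
}

# small architecture for fast training tests
tiny_arch <- function() {
  architecture(input_shape = c(8L, 12L, 12L, 1L), filters = 4L,
               dense_units = 8L, dropout_rate = 0)
}

tiny_stack <- function(seed, label = "control") {
  random_stack(seed, n_real = 8L, depth = 8L, size = 12L, label = label)
}

# brute-force AUC oracle: enumerate all positive/negative pairs, ties 1/2
auc_bruteforce <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
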