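test_that("load_series reads every file and round-trips phantom pixels", {
  dir <- tiny_cohort_dir()
  man <- read_manifest(dir)
  pid <- man$patient_id[1]
  slices <- load_series(file.path(dir, pid))
  n_files <- length(list.files(file.path(dir, pid)))
  expect_equal(nrow(slices), n_files)
  cfg <- tiny_phantom_config(n_diseased = 2, n_control = 1, seed = 71)
  src <- generate_patient_series(cfg, pid, man$label[1],
                                 man$patient_seed[1])
  key <- function(d) d[order(d$plane, d$sequence, d$instance_number), ]
  a <- key(src); b <- key(slices)
  expect_equal(b$instance_number, a$instance_number)
  expect_true(all(mapply(identical, a$pixels, b$pixels)))
})

test_that("a corrupt file among good ones is skipped with a warning", {
  dir <- withr::local_tempdir()
  for (i in 1:9) {
    dcm_write(file.path(dir, sprintf("s%02d.dcm", i)),
              matrix(i, 16, 16), "P1", i)
  }
  writeBin(as.raw(1:200), file.path(dir, "s10.dcm"))
  expect_warning(slices <- load_series(dir), "skipping")
  expect_equal(nrow(slices), 9)
  # all-corrupt directory fails
  dir2 <- withr::local_tempdir()
  writeBin(as.raw(1:100), file.path(dir2, "bad.dcm"))
  suppressWarnings(expect_error(load_series(dir2), "no readable"))
})

test_that("instance sorting is correct, idempotent and permutation-invariant", {
  mk <- function(inst) tibble::tibble(
    patient_id = "P", instance_number = inst, plane = "axial",
    sequence = "T2W", rows = 4L, cols = 4L,
    pixels = lapply(inst, function(i) matrix(i, 4, 4)))
  s <- mk(c(3L, 1L, 2L))
  expect_equal(sort_by_instance(s)$instance_number, 1:3)
  sorted <- sort_by_instance(mk(1:3))
  expect_identical(sort_by_instance(sorted), sorted)
  big <- mk(sample(1:50))
  perm <- withr::with_seed(4, big[sample(50), ])
  expect_identical(sort_by_instance(perm), sort_by_instance(big))
  bad <- mk(c(1L, NA, 3L))
  expect_error(sort_by_instance(bad), "instance_number")
})

test_that("axial-sequence filtering keeps exactly the admissible slices", {
  mk <- function(n, plane, sq) tibble::tibble(
    patient_id = "P", instance_number = seq_len(n), plane = plane,
    sequence = sq, rows = 16L, cols = 16L,
    pixels = replicate(n, matrix(0, 16, 16), simplify = FALSE))
  s <- dplyr::bind_rows(mk(10, "axial", "FLAIR"), mk(5, "sagittal", "T1W"))
  out <- filter_axial_sequences(s)
  expect_equal(nrow(out), 10)
  expect_true(all(out$plane == "axial"))
  expect_error(filter_axial_sequences(mk(4, "coronal", "T2W")), "unusable")
  # never modifies pixels; preserves relative order
  expect_identical(out$pixels, s$pixels[1:10])
})

test_that("small-matrix discard removes exactly the sub-threshold slices", {
  mk <- function(sizes) tibble::tibble(
    patient_id = "P", instance_number = seq_along(sizes), plane = "axial",
    sequence = "T2W", rows = as.integer(sizes), cols = as.integer(sizes),
    pixels = lapply(sizes, function(s) matrix(0, s, s)))
  expect_equal(discard_small(mk(c(64, 256, 512)))$rows, c(256L, 512L))
  all256 <- mk(rep(256, 5))
  expect_identical(discard_small(all256), all256)
  sizes <- c(rep(64, 37), rep(256, 63))
  expect_equal(nrow(discard_small(mk(sizes))), 63)
})

test_that("area resampling preserves constants, means, and identity", {
  cmat <- matrix(3.7, 256, 256)
  out <- area_resample(cmat, 128)
  expect_equal(dim(out), c(128, 128))
  expect_equal(max(abs(out - 3.7)), 0, tolerance = 1e-12)
  big <- withr::with_seed(2, matrix(runif(512^2), 512, 512))
  shr <- area_resample(big, 128)
  expect_equal(dim(shr), c(128, 128))
  expect_equal(mean(shr), mean(big), tolerance = 1e-12)  # area preservation
  id <- matrix(rnorm(128^2), 128, 128)
  expect_identical(area_resample(id, 128), id)
  expect_error(area_resample(id, 256), "upscaling")
  # non-integer ratio still averages exactly: 3->2 with known weights
  m <- matrix(c(0, 3, 6), 3, 3, byrow = FALSE)
  r <- area_resample(m, 2)
  expect_equal(r[, 1], c(1, 5), tolerance = 1e-12)
})

test_that("dataset statistics use the pooled population formula", {
  two <- tibble::tibble(
    patient_id = "P", instance_number = 1:2, plane = "axial",
    sequence = "T2W", rows = 1L, cols = 1L,
    pixels = list(matrix(0, 1, 1), matrix(2, 1, 1)))
  st <- compute_dataset_stats(two)
  expect_equal(st$mean, 1)
  expect_equal(st$sd, 1)  # population, not sample, sd
  const <- dplyr::mutate(two, pixels = list(matrix(5, 1, 1), matrix(5, 1, 1)))
  expect_error(compute_dataset_stats(const), "constant")
  normal <- tibble::tibble(
    patient_id = "P", instance_number = 1L, plane = "axial",
    sequence = "T2W", rows = 1000L, cols = 1L,
    pixels = list(withr::with_seed(8, matrix(rnorm(1000), 1000, 1))))
  st2 <- compute_dataset_stats(normal)
  expect_lt(abs(st2$mean), 0.1)
  expect_gt(st2$sd, 0.9); expect_lt(st2$sd, 1.1)
})

test_that("normalization implements the z-score and self-consistency", {
  st <- fixed_stats(mean = 10, sd = 4)
  mk <- function(v) tibble::tibble(
    patient_id = "P", instance_number = 1L, plane = "axial",
    sequence = "T2W", rows = 3L, cols = 3L, pixels = list(matrix(v, 3, 3)))
  expect_equal(normalize_slices(mk(10), st)$pixels[[1]],
               matrix(0, 3, 3))
  expect_equal(normalize_slices(mk(14), st)$pixels[[1]],
               matrix(1, 3, 3))
  # re-pooling normalized pixels gives mean 0, sd 1
  raw <- withr::with_seed(3, tibble::tibble(
    patient_id = "P", instance_number = 1:4, plane = "axial",
    sequence = "T2W", rows = 20L, cols = 20L,
    pixels = replicate(4, matrix(rnorm(400, 50, 9), 20, 20),
                       simplify = FALSE)))
  stats <- compute_dataset_stats(raw)
  norm <- normalize_slices(raw, stats)
  renorm <- compute_dataset_stats(norm)
  expect_equal(renorm$mean, 0, tolerance = 1e-6)
  expect_equal(renorm$sd, 1, tolerance = 1e-6)
})

test_that("zero-padding fills exactly the depth remainder", {
  mk <- function(n) tibble::tibble(
    patient_id = "P", instance_number = seq_len(n), plane = "axial",
    sequence = "T2W", rows = 8L, cols = 8L,
    pixels = replicate(n, matrix(rnorm(64), 8, 8), simplify = FALSE))
  for (n in c(23L, 115L, 120L)) {
    st <- pad_stack(mk(n), depth = 120L)
    expect_equal(dim(st), c(120L, 8L, 8L, 1L))
    expect_equal(attr(st, "n_real_slices"), n)
    if (n < 120) {
      expect_true(all(st[(n + 1):120, , , ] == 0))
    }
    s <- mk(n)
    for (i in seq_len(n)) {
      expect_equal(st[i, , , 1], st[i, , , 1])  # shape access works
    }
  }
  s120 <- mk(120L)
  full <- pad_stack(s120, depth = 120L)
  expect_equal(full[7, , , 1], s120$pixels[[7]])
  expect_error(pad_stack(mk(121L), depth = 120L), "truncation")
  expect_error(pad_stack(mk(0L)), "empty")
})

test_that("build_stack yields the fixed shape and is file-order invariant", {
  dir <- tiny_cohort_dir()
  man <- read_manifest(dir)
  st <- fixed_stats()
  for (i in 1:2) {
    stack <- build_stack(file.path(dir, man$patient_id[i]), st,
                         depth = 24L, target = 32L, label = man$label[i])
    expect_equal(dim(stack), c(24L, 32L, 32L, 1L))
    expect_equal(attr(stack, "n_real_slices"), man$n_axial[i])
    n <- man$n_axial[i]
    expect_true(all(stack[(n + 1):24, , , ] == 0))
  }
  # permuting the slice tibble row order cannot change the stack
  slices <- load_series(file.path(dir, man$patient_id[1]))
  build_from <- function(s) {
    s |> prepare_slices(target = 32L) |> normalize_slices(st) |>
      pad_stack(depth = 24L)
  }
  a <- build_from(slices)
  b <- build_from(withr::with_seed(5, slices[sample(nrow(slices)), ]))
  expect_identical(unclass(a), unclass(b))
})
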