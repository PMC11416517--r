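test_that("degenerate slice interval forces the exact slice count", {
  cfg <- phantom_config(n_diseased = 1, n_control = 0,
                        slice_count_range = c(23L, 23L),
                        matrix_sizes = 256L, sequences = "FLAIR",
                        planes = "axial", seed = 1)
  s <- generate_patient_series(cfg, "P001", "diseased", 5)
  expect_equal(nrow(s), 23L)
  expect_true(all(s$plane == "axial" & s$sequence == "FLAIR"))
  expect_equal(s$instance_number, 1:23)
})

test_that("series generation is a pure function of its arguments", {
  cfg <- tiny_phantom_config()
  a <- generate_patient_series(cfg, "P009", "diseased", 33)
  b <- generate_patient_series(cfg, "P009", "diseased", 33)
  expect_identical(a, b)
  # and it does not disturb the caller's RNG stream
  withr::with_seed(1, {
    before <- runif(1)
  })
  withr::with_seed(1, {
    invisible(generate_patient_series(cfg, "P009", "control", 33))
    after <- runif(1)
  })
  expect_identical(before, after)
})

test_that("invalid labels and empty tag sets are rejected", {
  cfg <- tiny_phantom_config()
  expect_error(generate_patient_series(cfg, "P1", "sick", 1), "label")
  expect_error(phantom_config(sequences = character(0)), "sequences")
  expect_error(phantom_config(planes = character(0)), "planes")
  expect_error(phantom_config(n_diseased = 0, n_control = 0), "total")
  expect_error(phantom_config(lesion_contrast = 0), "lesion_contrast")
  expect_error(phantom_config(slice_count_range = c(0, 10)), "interval")
})

test_that("diseased lesion regions are brighter than matched control regions", {
  cfg <- tiny_phantom_config(lesion_contrast = 2)
  seed <- 91
  dis <- generate_patient_series(cfg, "Pd", "diseased", seed)
  ctl <- generate_patient_series(cfg, "Pd", "control", seed)
  mask <- stack_lesion_mask(cfg, "Pd", "diseased", seed,
                            depth = 24L, target = 256L)
  # pick a diseased axial FLAIR slice whose mask is non-empty
  geom_rows <- which(dis$plane == "axial" & dis$sequence == "FLAIR" &
                       dis$rows == 256)
  qual_dis <- dplyr::filter(dis, plane == "axial", rows >= 128)
  qual_ctl <- dplyr::filter(ctl, plane == "axial", rows >= 128)
  found <- FALSE
  for (k in seq_len(nrow(qual_dis))) {
    m <- mask[k, , ]
    if (qual_dis$sequence[k] == "FLAIR" && sum(m) > 20) {
      expect_gt(mean(qual_dis$pixels[[k]][m]), mean(qual_ctl$pixels[[k]][m]))
      found <- TRUE
    }
  }
  expect_true(found)
  expect_gt(length(geom_rows), 0)
})

test_that("lesion-region contrast margin grows with lesion_contrast", {
  margins <- sapply(c(1.5, 2.5, 3.5), function(ctr) {
    cfg <- tiny_phantom_config(n_diseased = 10, n_control = 10,
                               lesion_contrast = ctr, seed = 17)
    vals <- sapply(1:8, function(i) {
      seed <- 1000 + i
      dis <- generate_patient_series(cfg, "Px", "diseased", seed)
      ctl <- generate_patient_series(cfg, "Px", "control", seed)
      mask <- stack_lesion_mask(cfg, "Px", "diseased", seed,
                                depth = 24L, target = 256L)
      qd <- dplyr::filter(dis, plane == "axial", rows >= 128)
      qc <- dplyr::filter(ctl, plane == "axial", rows >= 128)
      num <- 0; den <- 0; nn <- 0
      for (k in seq_len(nrow(qd))) {
        m <- mask[k, , ]
        if (sum(m) > 0 && qd$sequence[k] %in% c("T2W", "FLAIR")) {
          num <- num + mean(qd$pixels[[k]][m])
          den <- den + mean(qc$pixels[[k]][m])
          nn <- nn + 1
        }
      }
      c(num, den) / max(nn, 1)
    })
    mean(vals[1, ] - vals[2, ])
  })
  expect_gt(margins[1], 0)
  expect_true(all(diff(margins) > 0))
})

test_that("cohort writing produces the manifest and per-patient files", {
  cfg <- tiny_phantom_config(n_diseased = 2, n_control = 1, seed = 3)
  dir <- withr::local_tempdir()
  man <- write_cohort(cfg, dir)
  expect_equal(nrow(man), 3)
  expect_equal(sum(man$label == "diseased"), 2)
  expect_identical(man, read_manifest(dir)[, names(man)],
                   ignore_attr = TRUE)
  for (pid in man$patient_id) {
    files <- list.files(file.path(dir, pid))
    expect_gt(length(files), 0)
    sizes <- sapply(file.path(dir, pid, files), function(f) dcm_read(f)$rows)
    expect_true(any(sizes == 64))   # scout slices present
    expect_true(any(sizes == 256))  # diagnostic slices present
  }
})

test_that("generated axial totals always lie within slice_count_range", {
  cfg <- phantom_config(n_diseased = 3, n_control = 2,
                        slice_count_range = c(23L, 115L), seed = 5)
  for (i in 1:5) {
    lab <- if (i <= 3) "diseased" else "control"
    s <- generate_patient_series(cfg, sprintf("P%d", i), lab, 500 + i)
    n_qual <- sum(s$plane == "axial" & s$rows >= 128)
    expect_gte(n_qual, 23L)
    expect_lte(n_qual, 115L)
  }
})

test_that("unwritable output path fails loudly", {
  expect_error(write_cohort(tiny_phantom_config(), "/proc/nope/cohort"),
               "write")
})
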