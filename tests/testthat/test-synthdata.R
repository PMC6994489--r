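test_that("empty field is background and noise only, with empty truth", {
  out <- generate_field(tiny_field_spec(n_cells = 0, seed = 3))
  expect_equal(nrow(out$truth), 0)
  for (ch in c("dapi", "cd45", "tra")) {
    m <- out$field[[ch]]
    expect_equal(dim(m), c(128, 128))
    # background 100 DN, noise sd 2: everything within a generous noise band
    expect_true(all(m > 80) && all(m < 120))
  }
})

test_that("noise-free control renders a constant background", {
  spec <- field_spec(height_px = 64, width_px = 64, n_cells = 0,
                     noise_sd = 0, rng_seed = 1)
  ctrl <- generate_negative_control(spec)
  expect_true(all(ctrl$tra == spec$background_level))
  expect_true(all(ctrl$cd45 == spec$background_level))
})

test_that("illumination gradient tilts the noise-free background", {
  spec <- field_spec(height_px = 64, width_px = 64, n_cells = 0,
                     noise_sd = 0, illumination_gradient = 0.2, rng_seed = 1)
  ctrl <- generate_negative_control(spec)
  expect_true(mean(ctrl$tra[, 1:8]) < mean(ctrl$tra[, 57:64]))
})

test_that("TRA channel carries signal only at TRA+ truth cells", {
  spec <- tiny_field_spec(n_cells = 10, seed = 7, tra_fraction = 0.25)
  out <- generate_field(spec)
  tru <- out$truth
  # supra-background TRA value at each truth centre
  at_centre <- out$field$tra[cbind(round(tru$row), round(tru$col))]
  expect_true(all(at_centre[tru$tra_positive] > 500))
  expect_true(all(at_centre[!tru$tra_positive] < 120))
  # number of bright blobs equals number of TRA+ cells
  lab <- tracell:::label_components(out$field$tra > 500, 8L)
  expect_equal(max(lab), sum(tru$tra_positive))
})

test_that("DAPI signal inside truth nuclei clears background by >= 5 noise SD", {
  spec <- tiny_field_spec(n_cells = 15, seed = 9)
  out <- generate_field(spec)
  tru <- out$truth
  for (i in seq_len(nrow(tru))) {
    h <- nrow(out$field$dapi)
    ii <- pmax(1, pmin(h, round(tru$row[i]) + (-2:2)))
    jj <- pmax(1, pmin(h, round(tru$col[i]) + (-2:2)))
    expect_gt(mean(out$field$dapi[ii, jj]),
              spec$background_level + 5 * spec$noise_sd)
  }
})

test_that("same seed gives bit-identical fields and truth; seeds differ otherwise", {
  a <- generate_field(tiny_field_spec(n_cells = 8, seed = 11, tra_fraction = 0.3))
  b <- generate_field(tiny_field_spec(n_cells = 8, seed = 11, tra_fraction = 0.3))
  d <- generate_field(tiny_field_spec(n_cells = 8, seed = 12, tra_fraction = 0.3))
  expect_identical(a$field$dapi, b$field$dapi)
  expect_identical(a$field$cd45, b$field$cd45)
  expect_identical(a$field$tra, b$field$tra)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$field$dapi, d$field$dapi))
  c1 <- generate_negative_control(tiny_field_spec(n_cells = 8, seed = 13))
  c2 <- generate_negative_control(tiny_field_spec(n_cells = 8, seed = 13))
  expect_identical(c1$tra, c2$tra)
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  r1 <- runif(1)
  set.seed(99)
  invisible(generate_field(tiny_field_spec(n_cells = 5, seed = 1)))
  r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("negative control has nuclei but no cell-associated TRA or CD45 signal", {
  spec <- field_spec(height_px = 256, width_px = 256, n_cells = 50, rng_seed = 5)
  ctrl <- generate_negative_control(spec)
  expect_gt(max(ctrl$dapi), 1000)
  # TRA maximum is a noise-tail value, far below any stain amplitude
  expect_lt(max(ctrl$tra), spec$background_level + 6 * spec$noise_sd)
  expect_lt(max(ctrl$cd45), spec$background_level + 6 * spec$noise_sd)
})

test_that("nuclei centres respect the two-radius minimum separation", {
  out <- generate_field(tiny_field_spec(n_cells = 20, seed = 21))
  tru <- out$truth
  d <- as.matrix(dist(cbind(tru$row, tru$col)))
  diag(d) <- Inf
  for (i in seq_len(nrow(tru))) {
    expect_true(all(d[i, ] >= 2 * pmax(tru$radius_px[i], tru$radius_px) - 1e-9))
  }
})

test_that("impossible density raises a placement-failure error", {
  expect_error(
    generate_field(field_spec(height_px = 64, width_px = 64, n_cells = 200,
                              rng_seed = 1)),
    "placement failure"
  )
})

test_that("cohort generation writes the expected layout and is deterministic", {
  d1 <- tempfile("cohortA")
  d2 <- tempfile("cohortB")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  design <- dplyr::bind_rows(
    patient_spec("pa", "healthy", n_fields = 2, n_control_fields = 1,
                 tra_fraction = 0, cells_per_field = 10,
                 height_px = 96, width_px = 96, rng_seed = 5),
    patient_spec("pb", "metastatic", n_fields = 1, n_control_fields = 1,
                 tra_fraction = 0.5, cd45low_given_tra = 0.5,
                 cells_per_field = 10, height_px = 96, width_px = 96,
                 rng_seed = 6)
  )
  t1 <- generate_cohort(design, d1)
  t2 <- generate_cohort(design, d2)
  expect_true(file.exists(file.path(d1, "pa", "field_02", "tra.tif")))
  expect_true(file.exists(file.path(d1, "pb", "control_01", "dapi.tif")))
  expect_true(file.exists(file.path(d1, "cells_truth.csv")))
  expect_identical(t1$cells_truth, t2$cells_truth)
  expect_identical(
    tools::md5sum(file.path(d1, "pb", "field_01", "dapi.tif"))[[1]],
    tools::md5sum(file.path(d2, "pb", "field_01", "dapi.tif"))[[1]]
  )
  # healthy patient with tra_fraction 0 has an all-negative truth table
  expect_equal(sum(t1$cells_truth$tra_positive[t1$cells_truth$patient_id == "pa"]), 0)
  # TIFF round trip is exact
  img <- read_channel_tiff(file.path(d1, "pb", "field_01", "dapi.tif"))
  pat <- tracell:::generate_patient(design[2, ])
  expect_identical(img, pat$fields[[1]]$dapi)
})

test_that("duplicate patient ids are rejected", {
  design <- dplyr::bind_rows(
    patient_spec("same", "healthy", cells_per_field = 5, n_fields = 1,
                 height_px = 96, width_px = 96),
    patient_spec("same", "healthy", cells_per_field = 5, n_fields = 1,
                 height_px = 96, width_px = 96)
  )
  expect_error(generate_cohort(design, tempfile()), "duplicate patient")
})

test_that("default design mirrors the study cohort structure", {
  design <- cohort_design_paper(seed = 4)
  expect_equal(nrow(design), 57)
  expect_equal(sum(design$group == "healthy"), 17)
  expect_equal(sum(design$group == "metastatic"), 26)
  expect_equal(sum(design$group == "localized"), 13)
  expect_equal(sum(design$group == "progressor"), 1)
  # printed per-group TRA+ fraction ranges
  expect_true(all(design$tra_fraction[design$group == "healthy"] <= 0.023))
  met <- design$tra_fraction[design$group == "metastatic"]
  expect_true(all(met >= 0.002 & met <= 0.136))
  loc <- design$tra_fraction[design$group == "localized"]
  expect_true(all(loc >= 2e-5 & loc <= 0.031))
  # CD45-low cells only in metastatic-like groups and two localized patients
  expect_true(all(design$cd45low_given_tra[design$group == "healthy"] == 0))
  expect_equal(sum(design$cd45low_given_tra[design$group == "localized"] > 0), 2)
  expect_true(all(design$cd45low_given_tra[design$group %in% c("metastatic", "progressor")] > 0))
  expect_identical(design, cohort_design_paper(seed = 4))
})
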