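# Hand-built per-cell record tables: the patient-level measures are pure
# table transformations, so they are tested directly against hand
# computations.
make_records <- function(patient = "p1", field = 1L, n, n_pos,
                         cd45_pos = 50, cd45_neg = 200) {
  tibble::tibble(
    patient_id = patient,
    field_index = field,
    cell_label = seq_len(n),
    tra_positive = c(rep(TRUE, n_pos), rep(FALSE, n - n_pos)),
    cd45_mean = c(rep(cd45_pos, length.out = n_pos),
                  rep(cd45_neg, length.out = n - n_pos))
  )
}

test_that("per-field TRA percentages and their spread match hand computation", {
  # one field, 2 TRA+ of 50 cells -> 4%
  r <- make_records(n = 50, n_pos = 2)
  out <- percent_tra(r)
  expect_equal(out$mean_pct_tra, 4)
  expect_equal(out$sd_pct_tra, 0)

  # two fields at 1% and 3% -> mean 2, population SD 1, sample SD sqrt(2)
  r2 <- dplyr::bind_rows(
    make_records(field = 1L, n = 100, n_pos = 1),
    make_records(field = 2L, n = 100, n_pos = 3)
  )
  out2 <- percent_tra(r2)
  expect_equal(out2$mean_pct_tra, 2)
  expect_equal(out2$sd_pct_tra, 1)
  out2b <- percent_tra(r2, pipeline_config(sd_method = "sample"))
  expect_equal(out2b$sd_pct_tra, sd(c(1, 3)))

  # all fields zero
  r3 <- dplyr::bind_rows(
    make_records(field = 1L, n = 40, n_pos = 0),
    make_records(field = 2L, n = 60, n_pos = 0)
  )
  out3 <- percent_tra(r3)
  expect_equal(out3$mean_pct_tra, 0)
  expect_equal(out3$sd_pct_tra, 0)
  expect_error(percent_tra(make_records(n = 10, n_pos = 0)[0, ]), "no cell records")
})

test_that("CD45 normalization divides by the TRA-negative mean", {
  r <- tibble::tibble(
    patient_id = "p1", field_index = 1L, cell_label = 1:3,
    tra_positive = c(TRUE, FALSE, FALSE),
    cd45_mean = c(50, 100, 300)
  )
  out <- normalize_cd45(r)
  expect_equal(out$cd45_norm, c(0.25, 0.5, 1.5))
  # TRA- cells average to exactly 1 by construction
  expect_equal(mean(out$cd45_norm[!out$tra_positive]), 1)

  # per-patient denominators are independent
  r2 <- dplyr::bind_rows(r, dplyr::mutate(r, patient_id = "p2", cd45_mean = cd45_mean * 10))
  out2 <- normalize_cd45(r2)
  expect_equal(out2$cd45_norm[out2$patient_id == "p2"], c(0.25, 0.5, 1.5))

  all_pos <- dplyr::mutate(r, tra_positive = TRUE)
  expect_error(normalize_cd45(all_pos), "no TRA-negative")
})

test_that("CD45-low counting is strictly below the cutoff and scales per 1000", {
  r <- make_records(n = 6000, n_pos = 10, cd45_pos = 150)
  r$cd45_mean[1:3] <- 10    # low TRA+ cells
  r$cd45_mean[4] <- 0.3 * 200  # exactly at the cutoff after normalization
  out <- cd45low_per_1000(normalize_cd45(r))
  # 3 qualifying among 6000 -> 0.5 per 1000; the boundary cell is excluded
  expect_equal(out$cd45low_count, 3L)
  expect_equal(out$cd45low_per_1000, 0.5)

  # brute-force filter agreement on a random table
  set.seed(31)
  rr <- make_records(n = 500, n_pos = 80)
  rr$cd45_mean <- runif(500, 0, 400)
  nn <- normalize_cd45(rr)
  out2 <- cd45low_per_1000(nn)
  brute <- sum(nn$tra_positive & nn$cd45_norm < 0.3)
  expect_equal(out2$cd45low_count, brute)
  expect_equal(out2$cd45low_per_1000, 1000 * brute / 500)
  expect_error(cd45low_per_1000(rr), "normalize_cd45")
})

test_that("rates are invariant under duplicating every field", {
  set.seed(32)
  r <- make_records(n = 400, n_pos = 12)
  r$cd45_mean <- runif(400, 0, 400)
  doubled <- dplyr::bind_rows(r, dplyr::mutate(r, field_index = 2L))
  a <- cd45low_per_1000(normalize_cd45(r))
  b <- cd45low_per_1000(normalize_cd45(doubled))
  expect_equal(a$cd45low_per_1000, b$cd45low_per_1000)
  expect_equal(percent_tra(r)$mean_pct_tra, percent_tra(doubled)$mean_pct_tra)
})

test_that("CD45 difference requires three TRA+ cells and matches hand values", {
  # 2 TRA+ cells -> excluded
  r <- make_records(n = 50, n_pos = 2)
  out <- cd45_difference(normalize_cd45(r))
  expect_false(out$included_in_diff)
  expect_true(is.na(out$cd45_diff))

  # TRA+ normalized levels {0.7, 0.8, 0.9} -> difference -0.2
  r2 <- tibble::tibble(
    patient_id = "p1", field_index = 1L, cell_label = 1:7,
    tra_positive = c(TRUE, TRUE, TRUE, rep(FALSE, 4)),
    cd45_mean = c(70, 80, 90, rep(100, 4))
  )
  out2 <- cd45_difference(normalize_cd45(r2))
  expect_true(out2$included_in_diff)
  expect_equal(out2$cd45_diff, -0.2)

  # all TRA+ above the TRA- level -> positive difference
  r3 <- dplyr::mutate(r2, cd45_mean = c(150, 160, 170, rep(100, 4)))
  expect_gt(cd45_difference(normalize_cd45(r3))$cd45_diff, 0)
})

test_that("summarize_patients assembles all measures with group labels", {
  r <- dplyr::bind_rows(
    make_records("a", n = 100, n_pos = 5),
    make_records("b", n = 80, n_pos = 2)
  )
  groups <- tibble::tibble(patient_id = c("a", "b"),
                           group = c("metastatic", "healthy"))
  s <- summarize_patients(r, groups = groups)
  expect_equal(nrow(s), 2)
  expect_named(
    s,
    c("patient_id", "group", "n_fields", "mean_pct_tra", "sd_pct_tra",
      "n_cells", "cd45low_count", "cd45low_per_1000", "n_tra_pos",
      "cd45_diff", "included_in_diff", "pct_tra_per_field"),
    ignore.order = TRUE
  )
  expect_equal(s$included_in_diff, c(TRUE, FALSE))
})
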