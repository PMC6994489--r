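test_that("preprocessing flattens constant rasters and preserves blob maxima", {
  cfg <- small_cfg()
  flat <- matrix(57, 64, 64)
  expect_true(all(preprocess_dapi(flat, cfg) == 0))

  # Gaussian smoothing conserves total intensity of an interior point source
  spike <- matrix(0, 65, 65)
  spike[33, 33] <- 1000
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(spike), sigma = 1))
  expect_equal(sum(sm), 1000, tolerance = 1e-6)

  # a disk on flat background stays the maximum after preprocessing
  img <- paint_disk(matrix(50, 96, 96), 48, 48, 6, amp = 500)
  prep <- preprocess_dapi(img, cfg)
  expect_true(all(prep >= 0))
  mx <- which(prep == max(prep), arr.ind = TRUE)
  expect_true(all(sqrt((mx[, 1] - 48)^2 + (mx[, 2] - 48)^2) <= 7))
  expect_error(preprocess_dapi(matrix(numeric(0), 0, 0), cfg), "empty")
})

test_that("otsu threshold matches the exhaustive-search oracle on random 8-bit images", {
  set.seed(101)
  for (k in 1:25) {
    # mixture images, uniform images, near-constant images
    x <- switch(1 + k %% 3,
      matrix(sample(0:255, 256, replace = TRUE), 16, 16),
      matrix(c(sample(0:60, 128, TRUE), sample(150:255, 128, TRUE)), 16, 16),
      matrix(sample(100:110, 256, TRUE), 16, 16)
    )
    expect_equal(otsu_threshold(x), otsu_brute(x))
  }
  expect_error(otsu_threshold(matrix(7, 4, 4)), "distinct")
})

test_that("otsu separates a bimodal image strictly between its modes, symmetrically", {
  x <- matrix(c(rep(0, 100), rep(200, 100)), 20, 10)
  t1 <- otsu_threshold(x)
  expect_true(t1 >= 0 && t1 < 200)
  expect_true(all((x > t1) == (x == 200)))
  # swapping foreground/background intensities flips the mask exactly
  y <- 200 - x
  t2 <- otsu_threshold(y)
  expect_identical((y > t2), !(x > t1))
})

test_that("rosin threshold matches its exhaustive-search oracle and flags degenerate peaks", {
  # tall peak at 0 decaying to a small tail
  set.seed(7)
  x <- matrix(c(rep(0, 600), rpois(400, 30)), 40, 25)
  expect_equal(rosin_threshold(x), rosin_brute(x))
  for (k in 1:20) {
    x <- matrix(c(rep(0, 500), sample(0:255, 200, TRUE, prob = exp(-(0:255) / 40))),
                10, 70)
    expect_equal(rosin_threshold(x), rosin_brute(x))
  }
  # histogram peaked at the maximum violates the unimodal-tail assumption
  bad <- matrix(c(rep(255, 200), 0:50), nrow = 1)
  expect_error(rosin_threshold(bad), "last non-empty bin")
  expect_error(rosin_threshold(matrix(3, 5, 5)), "constant")
})

test_that("rosin threshold falls at or below otsu on preprocessed DAPI fields", {
  cfg <- small_cfg()
  for (seed in c(31, 32, 33)) {
    out <- generate_field(tiny_field_spec(n_cells = 20, seed = seed))
    prep <- preprocess_dapi(out$field$dapi, cfg)
    expect_lte(rosin_threshold(prep), otsu_threshold(prep))
  }
})

test_that("two disjoint disks give exactly two labels", {
  img <- paint_disk(paint_disk(matrix(0, 80, 80), 25, 25, 7, 100),
                    55, 55, 7, 100)
  seg <- segment_nuclei(img, small_cfg())
  expect_equal(max(seg), 2)
})

test_that("touching pair above the median area is watershed-split; at/below is not", {
  cfg <- small_cfg()
  # 9 identical singletons + 1 touching pair: pair area > median -> 11 labels
  img <- matrix(0, 200, 200)
  centres <- expand.grid(r = c(30, 100, 170), c = c(30, 100, 170))
  for (i in 1:9) img <- paint_disk(img, centres$r[i], centres$c[i], 7, 100)
  img <- paint_disk(img, 60, 160, 7, 100)   # overlapping pair
  img <- paint_disk(img, 60, 170, 7, 100)
  seg <- segment_nuclei(img, cfg)
  expect_equal(max(seg), 11)

  # a small touching pair below the median of component areas stays merged
  img2 <- matrix(0, 200, 200)
  for (i in 1:9) img2 <- paint_disk(img2, centres$r[i], centres$c[i], 9, 100)
  img2 <- paint_disk(img2, 60, 160, 3, 100)
  img2 <- paint_disk(img2, 60, 164, 3, 100)
  seg2 <- segment_nuclei(img2, cfg)
  expect_equal(max(seg2), 10)
})

test_that("empty mask yields an empty label map, not an error", {
  seg <- segment_nuclei(matrix(0, 32, 32), small_cfg())
  expect_equal(max(seg), 0)
  cells <- dilated_cell_mask(matrix(0, 32, 32), seg, small_cfg())
  expect_equal(max(cells), 0)
})

test_that("connectivity setting controls diagonal merging", {
  m <- matrix(0, 10, 10)
  m[3, 3] <- 1
  m[4, 4] <- 1
  expect_equal(max(tracell:::label_components(m, 8L)), 1)
  expect_equal(max(tracell:::label_components(m, 4L)), 2)
})

test_that("label propagation matches the brute-force nearest-seed oracle", {
  set.seed(55)
  for (k in 1:5) {
    h <- 40; w <- 40
    seeds <- matrix(0L, h, w)
    seeds <- paint_disk(seeds, 12, 12, 4, 1)
    seeds <- paint_disk(seeds, 28, 25, 3, 2)
    seeds <- paint_disk(seeds, 15, 32, 2, 3)
    mask <- matrix(runif(h * w) < 0.4, h, w) | seeds > 0
    got <- tracell:::propagate_nearest(mask, seeds, 3)
    expect_identical(got, propagate_brute(mask, seeds))
  }
})

test_that("dilated cell mask covers seeds, conserves labels, grows with dilation", {
  cfg <- small_cfg()
  out <- generate_field(tiny_field_spec(n_cells = 15, seed = 41))
  prep <- preprocess_dapi(out$field$dapi, cfg)
  seeds <- segment_nuclei(prep, cfg)
  cells <- dilated_cell_mask(prep, seeds, cfg)
  n <- max(seeds)
  expect_equal(max(cells), n)
  expect_equal(sort(unique(as.vector(cells[cells > 0]))), 1:n)
  # every seed pixel keeps its label
  sidx <- which(seeds > 0)
  expect_identical(cells[sidx], seeds[sidx])
  # monotonicity in the dilation radius
  cells0 <- dilated_cell_mask(prep, seeds, small_cfg(dilation_px = 0L))
  cells8 <- dilated_cell_mask(prep, seeds, small_cfg(dilation_px = 8L))
  a0 <- tabulate(cells0[cells0 > 0], n)
  a5 <- tabulate(cells[cells > 0], n)
  a8 <- tabulate(cells8[cells8 > 0], n)
  expect_true(all(a5 >= a0))
  expect_true(all(a8 >= a5))
  # nucleus is contained in its cell: areas can only grow
  expect_true(all(a0 >= attr(seeds, "areas")))
})

test_that("segmentation recovers isolated synthetic nuclei one-to-one", {
  cfg <- small_cfg()
  out <- generate_field(field_spec(height_px = 256, width_px = 256,
                                   n_cells = 60, rng_seed = 77))
  seg <- segment_field(out$field, cfg)
  lab <- seg$seeds[cbind(round(out$truth$row), round(out$truth$col))]
  matched <- sum(lab > 0 & !duplicated(lab))
  expect_gte(matched / nrow(out$truth), 0.95)
})
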