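# Independent brute-force oracles, kept deliberately naive (loops, direct
# formulas) so they share no code path with the implementation.

# Otsu: exhaustive search over all integer candidate thresholds of an 8-bit
# image, minimizing the weighted within-class variance; ties go to the
# smallest threshold. Population variance (divisor n).
otsu_brute <- function(x) {
  x <- as.vector(x)
  pop_var <- function(v) if (length(v) <= 1) 0 else mean((v - mean(v))^2)
  best_t <- NA_real_
  best_w <- Inf
  for (t in 0:254) {
    lo <- x[x <= t]
    hi <- x[x > t]
    if (length(lo) == 0 || length(hi) == 0) next
    wcv <- (length(lo) * pop_var(lo) + length(hi) * pop_var(hi)) / length(x)
    if (wcv < best_w - 1e-12) {
      best_w <- wcv
      best_t <- t
    }
  }
  best_t
}

# Rosin: exhaustive search over histogram bins for the maximal perpendicular
# distance from the chord joining the peak bin to the last non-empty bin,
# using the full point-to-line distance formula.
rosin_brute <- function(x, n_bins = 256L) {
  rng <- range(x)
  h <- hist(as.vector(x), breaks = seq(rng[1], rng[2], length.out = n_bins + 1),
            plot = FALSE)
  counts <- h$counts
  peak <- which.max(counts)
  last <- max(which(counts > 0))
  stopifnot(peak < last)
  p1 <- c(peak, counts[peak])
  p2 <- c(last, counts[last])
  len <- sqrt(sum((p2 - p1)^2))
  best_i <- peak
  best_d <- -Inf
  for (i in peak:last) {
    d <- abs((p2[1] - p1[1]) * (p1[2] - counts[i]) -
               (p1[1] - i) * (p2[2] - p1[2])) / len
    if (d > best_d + 1e-12) {
      best_d <- d
      best_i <- i
    }
  }
  h$mids[best_i]
}

# AUC: direct concordant-pair count with half credit for ties.
auc_brute <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg) {
    s <- s + (p > n) + 0.5 * (p == n)
  }
  s / (length(pos) * length(neg))
}

# Nearest-seed label propagation: per-pixel loop over every seed pixel,
# minimum Euclidean distance, ties to the lowest label.
propagate_brute <- function(mask, seeds) {
  h <- nrow(mask); w <- ncol(mask)
  sidx <- which(seeds > 0)
  srow <- (sidx - 1) %% h + 1
  scol <- (sidx - 1) %/% h + 1
  slab <- seeds[sidx]
  out <- matrix(0L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (!mask[i, j]) next
    d2 <- (srow - i)^2 + (scol - j)^2
    dmin <- min(d2)
    out[i, j] <- as.integer(min(slab[d2 == dmin]))
  }
  out
}

# Calibration: exhaustive scan over all distinct control TRA intensities
# (ascending) for the smallest threshold giving zero TRA+ calls on every
# control field.
calibrate_brute <- function(control_fields, cfg = pipeline_config()) {
  segs <- lapply(control_fields, segment_field, cfg = cfg)
  vals <- sort(unique(unlist(lapply(seq_along(control_fields), function(i) {
    f <- control_fields[[i]]
    f$tra[segs[[i]]$cells > 0]
  }))))
  for (t in vals) {
    if (t <= 0) next
    npos <- sum(vapply(seq_along(control_fields), function(i) {
      sum(call_tra(control_fields[[i]]$tra, segs[[i]]$cells, t, cfg)$tra_positive)
    }, numeric(1)))
    if (npos == 0) return(t)
  }
  max(vals) + 1
}

# Paint a hard-edged disk of value `amp` onto a matrix (used to build
# deterministic rasters for segmentation tests).
paint_disk <- function(m, r0, c0, radius, amp = 1) {
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if ((i - r0)^2 + (j - c0)^2 <= radius^2) m[i, j] <- amp
  }
  m
}
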