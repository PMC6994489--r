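#' Preprocess a DAPI image
#'
#' Gaussian smoothing followed by morphological top-hat background
#' subtraction (subtracting a grayscale opening with a disc much larger than
#' a nucleus), clipped at zero. This flattens uneven illumination while
#' preserving nucleus-scale structure.
#'
#' @param dapi 2-D numeric matrix of nonnegative intensities.
#' @param cfg A [pipeline_config()] (uses `gaussian_sigma_px` and
#'   `bg_subtract_radius_px`).
#' @return A nonnegative numeric matrix of the same size.
#' @export
preprocess_dapi <- function(dapi, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  dapi <- as_matrix_2d(dapi, "dapi")
  stop_if_empty_raster(dapi)
  if (any(dapi < 0)) stop("dapi raster must be nonnegative")
  sm <- EBImage::imageData(EBImage::gblur(
    EBImage::Image(dapi), sigma = cfg$gaussian_sigma_px
  ))
  # Pad with edge replication before the grayscale opening so the border is
  # not treated as zero-valued background.
  r <- cfg$bg_subtract_radius_px
  padded <- pad_replicate(sm, r)
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  # grayscale morphology in EBImage clamps to [0, 1]; opening commutes with
  # positive scaling, so normalise and restore
  scale <- max(padded, 1e-12)
  bg <- scale * EBImage::imageData(EBImage::opening(padded / scale, brush))
  bg <- bg[(r + 1):(r + nrow(sm)), (r + 1):(r + ncol(sm))]
  out <- sm - bg
  out[out < 0] <- 0
  out
}

pad_replicate <- function(m, r) {
  ri <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
  ci <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
  m[ri, ci]
}

#' Otsu threshold
#'
#' Returns the intensity minimizing the weighted within-class variance over
#' the observed pixel values (equivalently, maximizing between-class
#' variance). Pixels with value less than or equal to the returned threshold
#' form the background class. Candidates are the observed distinct values;
#' ties resolve to the smallest candidate.
#'
#' @param raster 2-D numeric matrix with at least two distinct values.
#' @return A scalar threshold.
#' @export
otsu_threshold <- function(raster) {
  raster <- as_matrix_2d(raster)
  stop_if_empty_raster(raster)
  r <- rle(sort(as.vector(raster)))
  v <- r$values
  if (length(v) < 2) stop("otsu_threshold: raster has fewer than 2 distinct values")
  cnt <- as.numeric(r$lengths)
  n <- sum(cnt)
  w0 <- cumsum(cnt)                    # background class: x <= v[k]
  s0 <- cumsum(cnt * v)
  tot <- s0[length(s0)]
  k <- seq_len(length(v) - 1L)
  mu0 <- s0[k] / w0[k]
  w1 <- n - w0[k]
  mu1 <- (tot - s0[k]) / w1
  between <- w0[k] * w1 * (mu0 - mu1)^2 # maximizing this minimizes within-class var
  v[k][which.max(between)]
}

#' Rosin (unimodal) threshold
#'
#' For a histogram dominated by a single peak with a decaying tail, draws
#' the chord from the highest histogram bin to the last non-empty bin and
#' returns the intensity of the bin with maximal perpendicular distance from
#' that chord. Uses 256 equal-width bins over the observed intensity range.
#' Suited to images where foreground is a small fraction of pixels, so that
#' the background forms the single mode.
#'
#' @param raster 2-D numeric matrix with at least two distinct values.
#' @param n_bins Number of histogram bins.
#' @return A scalar threshold (centre of the selected bin).
#' @export
rosin_threshold <- function(raster, n_bins = 256L) {
  raster <- as_matrix_2d(raster)
  stop_if_empty_raster(raster)
  x <- as.vector(raster)
  rng <- range(x)
  if (rng[1] == rng[2]) stop("rosin_threshold: raster is constant")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  counts <- h$counts
  mids <- h$mids
  peak <- which.max(counts)
  last <- max(which(counts > 0))
  if (peak >= last) {
    stop("rosin_threshold: histogram peak is at the last non-empty bin; ",
         "the unimodal assumption (decaying upper tail) does not hold")
  }
  idx <- peak:last
  # Perpendicular distance of (i, counts[i]) from the peak-to-tail chord,
  # computed in (bin index, count) coordinates.
  dx <- last - peak
  dy <- counts[last] - counts[peak]
  num <- abs(dy * (idx - peak) - dx * (counts[idx] - counts[peak]))
  best <- idx[which.max(num)]
  mids[best]
}

# Connected components of a binary mask. EBImage::bwlabel is 4-connected;
# for 8-connectivity, labels touching diagonally are merged with a
# union-find pass over the label adjacency pairs. Labels are renumbered
# 1..N in row-major order of each component's first pixel.
label_components <- function(mask, connectivity = 8L) {
  mask <- (as_matrix_2d(mask) > 0)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  storage.mode(lab) <- "integer"
  nlab <- max(lab)
  if (nlab > 0 && connectivity == 8L) {
    h <- nrow(lab); w <- ncol(lab)
    # Diagonal neighbour pairs (down-right and down-left shifts).
    a1 <- lab[-h, -w]; b1 <- lab[-1, -1]
    a2 <- lab[-h, -1]; b2 <- lab[-1, -w]
    keep1 <- a1 > 0 & b1 > 0 & a1 != b1
    keep2 <- a2 > 0 & b2 > 0 & a2 != b2
    pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
    if (nrow(pairs) > 0) {
      parent <- seq_len(nlab)
      find <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      for (r in seq_len(nrow(pairs))) {
        ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(nlab), find, integer(1))
      lab[lab > 0] <- root[lab[lab > 0]]
    }
  }
  relabel_rowmajor(lab)
}

# Renumber positive labels 1..N by row-major order of first occurrence.
# R matrices are column-major, so "row-major first pixel" is computed
# explicitly from (row, col).
relabel_rowmajor <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  if (length(u) == 0) return(lab)
  idx <- which(lab > 0)
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  key <- (rows - 1L) * ncol(lab) + cols      # row-major rank
  first <- tapply(key, factor(lab[idx], levels = u), min)
  new_ids <- integer(max(u))
  new_ids[u[order(first)]] <- seq_along(u)
  lab[idx] <- new_ids[lab[idx]]
  lab
}

#' Segment nuclei from a preprocessed DAPI image
#'
#' Otsu-thresholds the preprocessed image into a nuclear mask, labels
#' connected components, and re-splits merged nuclei by watershed on the
#' Euclidean distance transform. For efficiency, only components whose area
#' exceeds the median component area are considered for watershed; smaller
#' components pass through unchanged. The result is the seed label map used
#' for downstream label propagation.
#'
#' @param preprocessed Output of [preprocess_dapi()].
#' @param cfg A [pipeline_config()].
#' @return An integer label matrix (0 = background, labels 1..N), with
#'   attribute `areas` giving per-label pixel areas. Class
#'   `tracell_labels`.
#' @export
segment_nuclei <- function(preprocessed, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  x <- as_matrix_2d(preprocessed, "preprocessed")
  stop_if_empty_raster(x)
  if (length(unique(as.vector(x))) < 2) {
    # Constant (e.g. fully subtracted) image: no nuclei.
    return(new_labels(matrix(0L, nrow(x), ncol(x))))
  }
  thr <- otsu_threshold(x)
  mask <- x > thr
  lab <- label_components(mask, cfg$connectivity)
  nlab <- max(lab)
  if (nlab == 0) return(new_labels(lab))

  areas <- tabulate(lab[lab > 0], nbins = nlab)
  med <- stats::median(areas)
  big <- which(areas > med)
  if (length(big) > 0) {
    next_id <- nlab
    h <- nrow(lab); w <- ncol(lab)
    for (id in big) {
      idx <- which(lab == id)
      rows <- (idx - 1L) %% h + 1L
      cols <- (idx - 1L) %/% h + 1L
      r0 <- max(1L, min(rows) - 1L); r1 <- min(h, max(rows) + 1L)
      c0 <- max(1L, min(cols) - 1L); c1 <- min(w, max(cols) + 1L)
      sub <- (lab[r0:r1, c0:c1] == id) * 1
      d <- EBImage::distmap(sub)
      ws <- EBImage::imageData(EBImage::watershed(
        d, tolerance = cfg$watershed_tolerance, ext = 1L
      ))
      k <- max(ws)
      if (k > 1) {
        piece <- lab[r0:r1, c0:c1]
        piece[ws == 1] <- id
        for (j in 2:k) {
          next_id <- next_id + 1L
          piece[ws == j] <- next_id
        }
        lab[r0:r1, c0:c1] <- piece
      }
    }
  }
  new_labels(relabel_rowmajor(lab))
}

new_labels <- function(lab) {
  storage.mode(lab) <- "integer"
  nlab <- if (length(lab) > 0) max(lab) else 0L
  attr(lab, "areas") <- if (nlab > 0) tabulate(lab[lab > 0], nbins = nlab) else integer(0)
  class(lab) <- c("tracell_labels", class(lab))
  lab
}

#' @export
print.tracell_labels <- function(x, ...) {
  cat(sprintf("<tracell label map> %d x %d px, %d labels\n",
              nrow(x), ncol(x), length(attr(x, "areas"))))
  invisible(x)
}

#' Build the dilated per-cell label map
#'
#' Constructs the cell mask by Rosin-thresholding the preprocessed DAPI
#' image (a weaker threshold than Otsu's, capturing the dimmer cell
#' margins), dilating it with a disc of radius `cfg$dilation_px` to cover
#' the whole cell surface, and uniting it with the seed mask. Every mask
#' pixel is then assigned the label of the Euclidean-nearest seed region;
#' seed pixels keep their own labels, and distance ties resolve to the
#' lowest label.
#'
#' @param preprocessed Output of [preprocess_dapi()].
#' @param seeds Seed label map from [segment_nuclei()].
#' @param cfg A [pipeline_config()].
#' @return An integer label matrix (class `tracell_labels`) with the same
#'   label vocabulary as `seeds`.
#' @export
dilated_cell_mask <- function(preprocessed, seeds, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  x <- as_matrix_2d(preprocessed, "preprocessed")
  if (!all(dim(x) == dim(seeds))) stop("preprocessed and seeds shapes differ")
  nlab <- length(attr(seeds, "areas"))
  if (is.null(nlab) || nlab == 0) nlab <- max(seeds)
  if (nlab == 0) return(new_labels(matrix(0L, nrow(x), ncol(x))))

  mask <- x > rosin_threshold(x)
  if (cfg$dilation_px > 0) {
    brush <- EBImage::makeBrush(2L * cfg$dilation_px + 1L, shape = "disc")
    mask <- EBImage::imageData(EBImage::dilate(EBImage::Image(mask * 1), brush)) > 0
  }
  mask <- mask | (seeds > 0)
  new_labels(propagate_nearest(mask, unclass_labels(seeds), nlab))
}

unclass_labels <- function(x) {
  attr(x, "areas") <- NULL
  class(x) <- "matrix"
  m <- matrix(as.integer(x), nrow(x), ncol(x))
  m
}

# Assign every TRUE pixel of `mask` the label of the nearest seed pixel
# (exact Euclidean distance to the seed region, ties to the lowest label).
# Per-label distance maps are evaluated on label bounding boxes expanded by
# the maximum seed distance occurring inside the mask, which keeps the sweep
# exact while touching only a small window per label.
propagate_nearest <- function(mask, seeds, nlab) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0L, h, w)
  if (!any(mask)) return(out)
  # Distance from every pixel to the nearest seed pixel of any label.
  d_all <- EBImage::imageData(EBImage::distmap((seeds == 0) * 1))
  margin <- ceiling(max(d_all[mask])) + 1L

  best <- matrix(Inf, h, w)
  idx <- which(seeds > 0)
  rows <- (idx - 1L) %% h + 1L
  cols <- (idx - 1L) %/% h + 1L
  labs <- seeds[idx]
  for (id in seq_len(nlab)) {
    sel <- labs == id
    if (!any(sel)) next
    r0 <- max(1L, min(rows[sel]) - margin); r1 <- min(h, max(rows[sel]) + margin)
    c0 <- max(1L, min(cols[sel]) - margin); c1 <- min(w, max(cols[sel]) + margin)
    sub_seed <- (seeds[r0:r1, c0:c1] == id)
    d <- EBImage::imageData(EBImage::distmap((!sub_seed) * 1))
    win_mask <- mask[r0:r1, c0:c1]
    upd <- win_mask & (d < best[r0:r1, c0:c1])
    if (any(upd)) {
      bb <- best[r0:r1, c0:c1]
      oo <- out[r0:r1, c0:c1]
      bb[upd] <- d[upd]
      oo[upd] <- id
      best[r0:r1, c0:c1] <- bb
      out[r0:r1, c0:c1] <- oo
    }
  }
  out
}
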