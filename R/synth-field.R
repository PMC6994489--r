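#' Specification of one synthetic field
#'
#' Describes a single imaged area of a PBMC slide: raster geometry, number of
#' nuclei, background and noise levels, and the composition of the cell
#' population (fraction of TRA-1-60 positive cells, and of CD45-low cells
#' among them). Defaults use a 512 x 512 px desk-scale field at the study's
#' 0.65 um/px sampling; the full-frame sCMOS geometry (2560 x 2160 px) is
#' available by changing `height_px`/`width_px`.
#'
#' Intensities are in camera digital numbers (DN) of a 16-bit detector; all
#' rendered images are rounded to integer DN, which mirrors real cameras and
#' keeps threshold calibration well defined.
#'
#' @param height_px,width_px Raster dimensions in pixels.
#' @param pixel_size_um Physical pixel size, micrometres.
#' @param n_cells Number of nuclei to place.
#' @param background_level Mean background intensity (DN).
#' @param noise_sd Additive Gaussian noise standard deviation (DN).
#' @param illumination_gradient Fractional left-to-right linear gain ramp in
#'   `[0, 1]`; 0 means flat illumination (constant-exposure, flat-fielded
#'   acquisition).
#' @param tra_fraction Probability that a cell is TRA-1-60 positive.
#' @param cd45low_given_tra Probability that a TRA+ cell belongs to the
#'   CD45-low class; TRA- cells are always CD45-high (normal leukocytes).
#' @param n_touching_pairs Number of cells (in addition to `n_cells`) placed
#'   as touching partners of existing cells, for testing watershed splitting.
#'   Default 0: nuclei are kept at least two radii apart.
#' @param poisson_noise If `TRUE`, replace additive Gaussian noise with
#'   Poisson shot noise on the noiseless image.
#' @param rng_seed Integer seed; identical seeds give bit-identical fields.
#' @return A list of class `tracell_field_spec`.
#' @export
field_spec <- function(height_px = 512L, width_px = 512L,
                       pixel_size_um = 0.65,
                       n_cells = 100L,
                       background_level = 100,
                       noise_sd = 2,
                       illumination_gradient = 0,
                       tra_fraction = 0,
                       cd45low_given_tra = 0,
                       n_touching_pairs = 0L,
                       poisson_noise = FALSE,
                       rng_seed = 1L) {
  stopifnot(
    height_px >= 16, width_px >= 16,
    pixel_size_um > 0,
    n_cells >= 0,
    background_level >= 0, noise_sd >= 0,
    illumination_gradient >= 0, illumination_gradient <= 1,
    tra_fraction >= 0, tra_fraction <= 1,
    cd45low_given_tra >= 0, cd45low_given_tra <= 1,
    n_touching_pairs >= 0
  )
  structure(
    list(
      height_px = as.integer(height_px), width_px = as.integer(width_px),
      pixel_size_um = pixel_size_um,
      n_cells = as.integer(n_cells),
      background_level = background_level,
      noise_sd = noise_sd,
      illumination_gradient = illumination_gradient,
      tra_fraction = tra_fraction,
      cd45low_given_tra = cd45low_given_tra,
      n_touching_pairs = as.integer(n_touching_pairs),
      poisson_noise = poisson_noise,
      rng_seed = as.integer(rng_seed)
    ),
    class = "tracell_field_spec"
  )
}

#' Per-class intensity distributions for synthetic cells
#'
#' Amplitudes are added on top of the field background before noise. The
#' CD45-low amplitude defaults to one noise standard deviation above
#' background (an "almost undetectable" level), while the CD45-high level is
#' ten times the low *level* (background + 1 SD), emulating normal
#' leukocytes. TRA+ cells of the CD45-high class get their CD45 amplitude
#' multiplied by `tra_cd45_boost`, reproducing the elevated CD45 observed on
#' TRA+ cells of healthy donors.
#'
#' `NULL` amplitude entries are resolved against the field's background and
#' noise at generation time.
#'
#' @param radius_mean_px,radius_sd_px Nucleus radius distribution (pixels);
#'   the default 5.5 px corresponds to a ~7 um nuclear diameter at
#'   0.65 um/px.
#' @param dapi_amp,tra_amp Mean signal amplitudes (DN) for nuclei and for the
#'   TRA-1-60 surface stain of positive cells.
#' @param cd45_low_amp,cd45_high_amp Mean CD45 amplitudes (DN) of the two
#'   CD45 classes; `NULL` means derive from background and noise as above.
#' @param amp_cv Coefficient of variation of all per-cell amplitudes
#'   (log-normal).
#' @param tra_cd45_boost CD45 multiplier for TRA+/CD45-high cells.
#' @param surface_margin_px Extra radius (pixels) of the surface-stain disk
#'   (CD45, TRA) beyond the nucleus, matching the 5-px mask dilation used by
#'   the analysis.
#' @param smoothing_sigma Gaussian sigma (pixels) applied to rendered disks.
#' @return A list of class `tracell_intensity_params`.
#' @export
intensity_params <- function(radius_mean_px = 4.2, radius_sd_px = 0.3,
                             dapi_amp = 2000, tra_amp = 1500,
                             cd45_low_amp = NULL, cd45_high_amp = NULL,
                             amp_cv = 0.15,
                             tra_cd45_boost = 1.4,
                             surface_margin_px = 2,
                             smoothing_sigma = 0.8) {
  stopifnot(radius_mean_px > 0, radius_sd_px >= 0, dapi_amp > 0, tra_amp > 0,
            amp_cv >= 0, tra_cd45_boost > 0, surface_margin_px >= 0,
            smoothing_sigma > 0)
  structure(
    list(
      radius_mean_px = radius_mean_px, radius_sd_px = radius_sd_px,
      dapi_amp = dapi_amp, tra_amp = tra_amp,
      cd45_low_amp = cd45_low_amp, cd45_high_amp = cd45_high_amp,
      amp_cv = amp_cv, tra_cd45_boost = tra_cd45_boost,
      surface_margin_px = surface_margin_px,
      smoothing_sigma = smoothing_sigma
    ),
    class = "tracell_intensity_params"
  )
}

# Resolve NULL CD45 amplitudes against the field background/noise. The low
# class sits one noise SD above background ("almost undetectable"); the high
# class is set so that the *measured* mean inside a dilated cell mask (where
# the stain covers only part of the mask and background dominates the rest)
# lands several-fold above background, as CD45-FITC does on normal
# leukocytes.
resolve_cd45_amps <- function(params, spec) {
  low_level <- spec$background_level + max(spec$noise_sd, 1)
  if (is.null(params$cd45_low_amp)) {
    params$cd45_low_amp <- low_level - spec$background_level
  }
  if (is.null(params$cd45_high_amp)) {
    params$cd45_high_amp <- 20 * low_level - spec$background_level
  }
  params
}

# Dart-throwing placement. Centres are kept at least
# max(2 * max(radius_i, radius_j), radius_i + radius_j + extra_sep) apart:
# never closer than two radii, plus enough clearance (`extra_sep`, derived
# from the surface-stain footprint) that one cell's suprathreshold stain
# cannot reach into a neighbour's propagated mask. Returns a data frame
# row, col (1-based pixel indices) or errors if the requested density
# cannot be placed.
place_nuclei <- function(n, height, width, radii, extra_sep = 0,
                         max_attempts_per_cell = 2000) {
  rows <- numeric(n)
  cols <- numeric(n)
  if (n == 0) return(data.frame(row = rows, col = cols))
  margin <- ceiling(radii) + 2
  placed <- 0L
  attempts <- 0L
  max_attempts <- max_attempts_per_cell * n
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(sprintf(
        "placement failure: could only place %d of %d nuclei at the requested density",
        placed, n
      ))
    }
    i <- placed + 1L
    r <- margin[i] + stats::runif(1) * (height - 2 * margin[i])
    c <- margin[i] + stats::runif(1) * (width - 2 * margin[i])
    if (placed > 0L) {
      j <- seq_len(placed)
      mindist <- pmax(2 * pmax(radii[j], radii[i]),
                      radii[j] + radii[i] + extra_sep)
      if (any((rows[j] - r)^2 + (cols[j] - c)^2 < mindist^2)) next
    }
    rows[i] <- r
    cols[i] <- c
    placed <- i
  }
  data.frame(row = rows, col = cols)
}

# Add amp * disk(radius) centred at (r0, c0) into accumulator matrix `acc`.
add_disk <- function(acc, r0, c0, radius, amp) {
  h <- nrow(acc); w <- ncol(acc)
  i0 <- max(1L, floor(r0 - radius)); i1 <- min(h, ceiling(r0 + radius))
  j0 <- max(1L, floor(c0 - radius)); j1 <- min(w, ceiling(c0 + radius))
  if (i0 > i1 || j0 > j1) return(acc)
  ii <- i0:i1; jj <- j0:j1
  d2 <- outer((ii - r0)^2, (jj - c0)^2, "+")
  acc[ii, jj] <- acc[ii, jj] + amp * (d2 <= radius^2)
  acc
}

# Linear left-to-right illumination gain field.
gain_field <- function(height, width, gradient) {
  if (gradient == 0) return(1)
  g <- 1 + gradient * (((seq_len(width) - 1) / max(width - 1, 1)) - 0.5)
  matrix(g, nrow = height, ncol = width, byrow = TRUE)
}

# Render one channel: (background + smoothed signal) * gain + noise,
# rounded to integer DN and clamped to the 16-bit range.
render_channel <- function(signal, spec, smoothing_sigma) {
  h <- spec$height_px; w <- spec$width_px
  if (is.null(signal)) {
    img <- matrix(0, h, w)
  } else if (max(signal) > 0) {
    img <- EBImage::imageData(EBImage::gblur(
      EBImage::Image(signal), sigma = smoothing_sigma
    ))
  } else {
    img <- signal
  }
  img <- (spec$background_level + img) * gain_field(h, w, spec$illumination_gradient)
  if (spec$poisson_noise) {
    img <- matrix(stats::rpois(h * w, lambda = pmax(img, 0)), h, w)
  } else if (spec$noise_sd > 0) {
    img <- img + stats::rnorm(h * w, sd = spec$noise_sd)
  }
  m <- round(img)
  m[m < 0] <- 0
  m[m > 65535] <- 65535
  storage.mode(m) <- "integer"
  m
}

generate_field_impl <- function(spec, params, channels) {
  params <- resolve_cd45_amps(params, spec)
  h <- spec$height_px; w <- spec$width_px
  n <- spec$n_cells

  radii <- pmax(1.5, stats::rnorm(n, params$radius_mean_px, params$radius_sd_px))
  # Clearance so that smoothed surface stain (margin + ~2.8 sigma of
  # Gaussian tail at typical amplitudes) stays out of neighbouring masks.
  extra_sep <- 2 * (params$surface_margin_px + 2.8 * params$smoothing_sigma) + 1
  centers <- place_nuclei(n, h, w, radii, extra_sep = extra_sep)

  # Optional touching partners appended after regular placement.
  if (spec$n_touching_pairs > 0) {
    if (spec$n_touching_pairs > n) {
      stop("n_touching_pairs cannot exceed n_cells")
    }
    hosts <- sample.int(n, spec$n_touching_pairs)
    for (hid in hosts) {
      r2 <- pmax(1.5, stats::rnorm(1, params$radius_mean_px, params$radius_sd_px))
      theta <- stats::runif(1, 0, 2 * pi)
      d <- 0.75 * (radii[hid] + r2)
      rr <- min(max(centers$row[hid] + d * sin(theta), ceiling(r2) + 2), h - ceiling(r2) - 2)
      cc <- min(max(centers$col[hid] + d * cos(theta), ceiling(r2) + 2), w - ceiling(r2) - 2)
      centers <- rbind(centers, data.frame(row = rr, col = cc))
      radii <- c(radii, r2)
    }
    n <- n + spec$n_touching_pairs
  }

  tra_positive <- stats::runif(n) < spec$tra_fraction
  cd45_class <- ifelse(
    tra_positive & stats::runif(n) < spec$cd45low_given_tra, "low", "high"
  )
  lnorm_amp <- function(mean_amp, n) {
    if (params$amp_cv == 0) return(rep(mean_amp, n))
    sdlog <- sqrt(log(1 + params$amp_cv^2))
    mean_amp * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  dapi_amp <- lnorm_amp(params$dapi_amp, n)
  tra_amp <- ifelse(tra_positive, lnorm_amp(params$tra_amp, n), 0)
  cd45_base <- ifelse(cd45_class == "low", params$cd45_low_amp, params$cd45_high_amp)
  cd45_boost <- ifelse(tra_positive & cd45_class == "high", params$tra_cd45_boost, 1)
  cd45_amp <- lnorm_amp(1, n) * cd45_base * cd45_boost

  truth <- tibble::tibble(
    cell_id = seq_len(n),
    row = centers$row, col = centers$col,
    radius_px = radii,
    tra_positive = tra_positive,
    cd45_class = cd45_class,
    dapi_amp = dapi_amp, cd45_amp = cd45_amp, tra_amp = tra_amp
  )
  if (n == 0) {
    truth <- truth[0, ]
  }

  sig <- list(dapi = NULL, cd45 = NULL, tra = NULL)
  for (ch in channels) sig[[ch]] <- matrix(0, h, w)
  margin <- params$surface_margin_px
  for (i in seq_len(n)) {
    if (!is.null(sig$dapi)) {
      sig$dapi <- add_disk(sig$dapi, centers$row[i], centers$col[i], radii[i], dapi_amp[i])
    }
    if (!is.null(sig$cd45)) {
      sig$cd45 <- add_disk(sig$cd45, centers$row[i], centers$col[i], radii[i] + margin, cd45_amp[i])
    }
    if (!is.null(sig$tra) && tra_positive[i]) {
      sig$tra <- add_disk(sig$tra, centers$row[i], centers$col[i], radii[i] + margin, tra_amp[i])
    }
  }

  field <- structure(
    list(
      dapi = render_channel(sig$dapi, spec, params$smoothing_sigma),
      cd45 = render_channel(sig$cd45, spec, params$smoothing_sigma),
      tra = render_channel(sig$tra, spec, params$smoothing_sigma),
      pixel_size_um = spec$pixel_size_um,
      height_px = h, width_px = w
    ),
    class = "tracell_field"
  )
  list(field = field, truth = truth)
}

#' Generate one synthetic three-channel field with ground truth
#'
#' Renders co-registered DAPI, CD45 and TRA-1-60 rasters for a population of
#' synthetic PBMCs. Nuclei are Gaussian-smoothed disks in the DAPI channel;
#' CD45 and TRA-1-60 are surface stains rendered on a disk
#' `surface_margin_px` larger than the nucleus. TRA-1-60 signal is present
#' only on TRA+ cells. The exact per-cell truth (centres, radii, classes,
#' amplitudes) is returned alongside the images.
#'
#' @param spec A [field_spec()].
#' @param params An [intensity_params()].
#' @return A list with elements `field` (class `tracell_field`: integer
#'   matrices `dapi`, `cd45`, `tra` plus geometry) and `truth` (a tibble with
#'   one row per cell).
#' @examples
#' out <- generate_field(field_spec(n_cells = 20, tra_fraction = 0.2, rng_seed = 7))
#' nrow(out$truth)
#' @export
generate_field <- function(spec, params = intensity_params()) {
  stopifnot(inherits(spec, "tracell_field_spec"))
  with_local_seed(spec$rng_seed, {
    generate_field_impl(spec, params, channels = c("dapi", "cd45", "tra"))
  })
}

#' Generate a negative-control field
#'
#' Emulates a secondary-antibody-only control: nuclei are present in the
#' DAPI channel, but the CD45 and TRA-1-60 channels carry only background
#' and noise with no cell-associated signal.
#'
#' @inheritParams generate_field
#' @return A `tracell_field` (no truth table: all cells are unstained).
#' @export
generate_negative_control <- function(spec, params = intensity_params()) {
  stopifnot(inherits(spec, "tracell_field_spec"))
  with_local_seed(spec$rng_seed, {
    generate_field_impl(spec, params, channels = "dapi")$field
  })
}

#' @export
print.tracell_field <- function(x, ...) {
  cat(sprintf(
    "<tracell field> %d x %d px at %.2f um/px; DAPI/CD45/TRA channels, integer DN\n",
    x$height_px, x$width_px, x$pixel_size_um
  ))
  invisible(x)
}
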