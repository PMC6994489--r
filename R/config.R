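#' Pipeline configuration
#'
#' Bundles the tunable constants of the image-analysis pipeline. Defaults
#' reproduce the published analysis settings: DAPI smoothing with a 1-pixel
#' Gaussian, a 5-pixel dilation of the nuclear mask to capture surface
#' staining, a minimum of 5 suprathreshold pixels for a TRA-1-60 call, a
#' normalized CD45 cutoff of 0.3 for the CD45-low class, and a minimum of
#' three TRA+ cells for a patient to enter the CD45-difference measure.
#'
#' @param gaussian_sigma_px Standard deviation (pixels) of the Gaussian
#'   smoothing applied to the DAPI channel before thresholding.
#' @param bg_subtract_radius_px Radius (pixels) of the disc structuring
#'   element used for morphological top-hat background subtraction. Should be
#'   much larger than a nucleus radius; 50 px corresponds to ~32 um at
#'   0.65 um/px.
#' @param dilation_px Radius (pixels) of the disc used to dilate the cell
#'   mask so the whole cell surface is covered.
#' @param min_tra_pixels Minimum number of suprathreshold TRA-1-60 pixels
#'   inside a cell mask for the cell to be called TRA+.
#' @param cd45low_cutoff Normalized CD45 level strictly below which a TRA+
#'   cell is classified CD45-low.
#' @param min_tra_cells_for_diff Minimum number of TRA+ cells a patient must
#'   have to be included in the CD45 intensity-difference measure.
#' @param connectivity Pixel connectivity for connected components, 4 or 8.
#' @param watershed_tolerance Minimum depth (in distance-transform units) an
#'   object minimum must have to seed a separate nucleus during watershed
#'   splitting of merged segmentations.
#' @param calibration Either `"detections"` (threshold is the smallest value
#'   for which the full calling rule yields zero TRA+ cells on the negative
#'   controls) or `"pixels"` (threshold is the maximum control pixel value
#'   inside any cell mask).
#' @param sd_method `"population"` (divisor n, as used for the per-field
#'   percentage spread) or `"sample"` (divisor n-1).
#' @param roc_ci `"hanley"` for the Hanley-McNeil normal-approximation
#'   confidence interval, or `"delong"` for DeLong variance estimates.
#'
#' @return A list of class `tracell_config`.
#' @examples
#' cfg <- pipeline_config()
#' cfg$min_tra_pixels
#' @export
pipeline_config <- function(gaussian_sigma_px = 1,
                            bg_subtract_radius_px = 50L,
                            dilation_px = 5L,
                            min_tra_pixels = 5L,
                            cd45low_cutoff = 0.3,
                            min_tra_cells_for_diff = 3L,
                            connectivity = 8L,
                            watershed_tolerance = 1,
                            calibration = c("detections", "pixels"),
                            sd_method = c("population", "sample"),
                            roc_ci = c("hanley", "delong")) {
  calibration <- match.arg(calibration)
  sd_method <- match.arg(sd_method)
  roc_ci <- match.arg(roc_ci)
  stopifnot(
    gaussian_sigma_px > 0,
    bg_subtract_radius_px > 0,
    dilation_px >= 0,
    min_tra_pixels >= 1,
    cd45low_cutoff > 0, cd45low_cutoff < 1,
    min_tra_cells_for_diff >= 1,
    connectivity %in% c(4L, 8L),
    watershed_tolerance > 0
  )
  structure(
    list(
      gaussian_sigma_px = gaussian_sigma_px,
      bg_subtract_radius_px = as.integer(bg_subtract_radius_px),
      dilation_px = as.integer(dilation_px),
      min_tra_pixels = as.integer(min_tra_pixels),
      cd45low_cutoff = cd45low_cutoff,
      min_tra_cells_for_diff = as.integer(min_tra_cells_for_diff),
      connectivity = as.integer(connectivity),
      watershed_tolerance = watershed_tolerance,
      calibration = calibration,
      sd_method = sd_method,
      roc_ci = roc_ci
    ),
    class = "tracell_config"
  )
}

#' @export
print.tracell_config <- function(x, ...) {
  cat("<tracell pipeline configuration>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected so typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML file whose keys are arguments of
#'   [pipeline_config()].
#' @return A `tracell_config` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

as_config <- function(cfg) {
  if (is.null(cfg)) return(pipeline_config())
  if (inherits(cfg, "tracell_config")) return(cfg)
  if (is.list(cfg)) return(do.call(pipeline_config, cfg))
  stop("`cfg` must be a tracell_config, a list of settings, or NULL")
}
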