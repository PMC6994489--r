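# Per-cell k-th largest pixel values of `raster` within each label.
# Returns a numeric vector indexed by label id (NA for labels with fewer
# than k pixels).
kth_largest_per_label <- function(raster, labels, k) {
  nlab <- max(labels)
  out <- rep(NA_real_, nlab)
  if (nlab == 0) return(out)
  idx <- which(labels > 0)
  vals <- split(raster[idx], labels[idx])
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (length(v) >= k) {
      out[as.integer(nm)] <- sort(v, decreasing = TRUE)[k]
    }
  }
  out
}

#' Segment one field end to end
#'
#' Convenience wrapper: preprocesses the DAPI channel, segments nuclei and
#' builds the dilated cell label map.
#'
#' @param field A `tracell_field`.
#' @param cfg A [pipeline_config()].
#' @return A list with `prep` (preprocessed DAPI), `seeds` (nucleus label
#'   map) and `cells` (dilated cell label map).
#' @export
segment_field <- function(field, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  prep <- preprocess_dapi(field$dapi, cfg)
  seeds <- segment_nuclei(prep, cfg)
  cells <- dilated_cell_mask(prep, seeds, cfg)
  list(prep = prep, seeds = seeds, cells = cells)
}

#' Calibrate the per-patient TRA-1-60 detection threshold
#'
#' Implements the negative-control calibration: the TRA threshold is set so
#' that the detection level on secondary-antibody-only controls is zero.
#' With `cfg$calibration = "detections"` (default) the returned threshold is
#' the smallest intensity `T` such that running the full TRA-calling rule
#' (strictly more than `T`, at least `cfg$min_tra_pixels` suprathreshold
#' pixels in a cell mask) on every control field yields zero TRA+ cells;
#' this equals the maximum over control cells of each cell's
#' `min_tra_pixels`-th largest TRA pixel. With `"pixels"`, it is the
#' maximum control TRA pixel value inside any cell mask.
#'
#' @param control_fields List of `tracell_field` control fields.
#' @param cfg A [pipeline_config()].
#' @param segmented Optional list of precomputed [segment_field()] results
#'   (one per control field), to avoid re-segmentation.
#' @return Scalar threshold (DN), guaranteed > 0.
#' @export
calibrate_tra_threshold <- function(control_fields, cfg = pipeline_config(),
                                    segmented = NULL) {
  cfg <- as_config(cfg)
  if (length(control_fields) == 0) stop("no control fields supplied")
  vmax <- 0
  any_cells <- FALSE
  for (i in seq_along(control_fields)) {
    fld <- control_fields[[i]]
    seg <- if (is.null(segmented)) segment_field(fld, cfg) else segmented[[i]]
    if (max(seg$cells) == 0) next
    any_cells <- TRUE
    k <- if (cfg$calibration == "detections") cfg$min_tra_pixels else 1L
    v <- kth_largest_per_label(fld$tra, seg$cells, k)
    v <- v[!is.na(v)]
    if (length(v) > 0) vmax <- max(vmax, v)
  }
  if (!any_cells) stop("no segmentable cells in any control field")
  if (vmax >= 65535) {
    stop("control TRA channel is saturated; cannot calibrate a threshold")
  }
  # All-zero controls: the smallest positive intensity step still yields
  # zero detections and keeps T > 0.
  max(vmax, 1)
}

#' Call TRA-1-60 positivity per cell
#'
#' Counts, for every cell of the dilated label map, the pixels of the
#' TRA-1-60 channel strictly above the calibrated threshold, and calls the
#' cell TRA+ when at least `cfg$min_tra_pixels` such pixels are present.
#'
#' @param tra TRA-1-60 channel matrix.
#' @param cells Dilated cell label map ([dilated_cell_mask()]).
#' @param threshold Calibrated intensity threshold (DN), > 0.
#' @param cfg A [pipeline_config()].
#' @return A tibble with `cell_label`, `tra_pixel_count`, `tra_positive`.
#' @export
call_tra <- function(tra, cells, threshold, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  tra <- as_matrix_2d(tra, "tra")
  if (!all(dim(tra) == dim(cells))) stop("tra raster and cell map shapes differ")
  if (threshold <= 0) stop("threshold must be positive")
  nlab <- max(cells)
  if (nlab == 0) {
    return(tibble::tibble(cell_label = integer(0),
                          tra_pixel_count = integer(0),
                          tra_positive = logical(0)))
  }
  hot <- cells[tra > threshold]
  counts <- tabulate(hot[hot > 0], nbins = nlab)
  tibble::tibble(
    cell_label = seq_len(nlab),
    tra_pixel_count = counts,
    tra_positive = counts >= cfg$min_tra_pixels
  )
}

#' Mean CD45 intensity per cell
#'
#' Arithmetic mean of the raw CD45 channel over each cell's dilated mask
#' pixels. No background subtraction is applied; the control-derived CD45
#' background is reported separately by [measure_cd45_background()].
#'
#' @param cd45 CD45 channel matrix.
#' @param cells Dilated cell label map.
#' @return A tibble with `cell_label` and `cd45_mean`.
#' @export
measure_cd45 <- function(cd45, cells) {
  cd45 <- as_matrix_2d(cd45, "cd45")
  if (!all(dim(cd45) == dim(cells))) stop("cd45 raster and cell map shapes differ")
  nlab <- max(cells)
  if (nlab == 0) {
    return(tibble::tibble(cell_label = integer(0), cd45_mean = numeric(0)))
  }
  idx <- which(cells > 0)
  lab <- factor(cells[idx], levels = seq_len(nlab))
  sums <- as.vector(rowsum(as.numeric(cd45[idx]), lab))
  areas <- tabulate(cells[idx], nbins = nlab)
  if (any(areas == 0)) stop("zero-area label encountered")
  tibble::tibble(cell_label = seq_len(nlab), cd45_mean = sums / areas)
}

#' CD45 background intensity from negative controls
#'
#' Mean over all control cells of the per-cell mean CD45 intensity inside
#' the dilated nuclei masks, i.e. the nonspecific (secondary-antibody-only)
#' staining level.
#'
#' @inheritParams calibrate_tra_threshold
#' @return Scalar background intensity (DN).
#' @export
measure_cd45_background <- function(control_fields, cfg = pipeline_config(),
                                    segmented = NULL) {
  cfg <- as_config(cfg)
  if (length(control_fields) == 0) stop("no control fields supplied")
  means <- numeric(0)
  for (i in seq_along(control_fields)) {
    fld <- control_fields[[i]]
    seg <- if (is.null(segmented)) segment_field(fld, cfg) else segmented[[i]]
    if (max(seg$cells) == 0) next
    means <- c(means, measure_cd45(fld$cd45, seg$cells)$cd45_mean)
  }
  if (length(means) == 0) stop("no segmentable cells in any control field")
  mean(means)
}

#' Quantify one patient: calibration plus per-cell records
#'
#' Segments the control fields to calibrate the TRA threshold and CD45
#' background, then segments every sample field, calls TRA positivity at
#' the calibrated threshold and measures per-cell CD45.
#'
#' @param patient_id Patient identifier attached to every record.
#' @param fields List of sample `tracell_field` objects.
#' @param control_fields List of control `tracell_field` objects.
#' @param cfg A [pipeline_config()].
#' @return A list with `cells` (tibble of per-cell records: `patient_id`,
#'   `field_index`, `cell_label`, `nucleus_area_px`, `cell_area_px`,
#'   `tra_pixel_count`, `tra_positive`, `cd45_mean`) and `calibration`
#'   (list: `patient_id`, `tra_threshold`, `cd45_background`,
#'   `n_control_fields`).
#' @export
quantify_patient <- function(patient_id, fields, control_fields,
                             cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  if (length(fields) == 0) stop("patient ", patient_id, " has no sample fields")
  ctrl_seg <- lapply(control_fields, segment_field, cfg = cfg)
  thr <- calibrate_tra_threshold(control_fields, cfg, segmented = ctrl_seg)
  bg <- measure_cd45_background(control_fields, cfg, segmented = ctrl_seg)
  recs <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    fld <- fields[[i]]
    seg <- segment_field(fld, cfg)
    nlab <- max(seg$cells)
    if (nlab == 0) next
    tra_tab <- call_tra(fld$tra, seg$cells, thr, cfg)
    cd45_tab <- measure_cd45(fld$cd45, seg$cells)
    recs[[i]] <- tibble::tibble(
      patient_id = patient_id,
      field_index = i,
      cell_label = seq_len(nlab),
      nucleus_area_px = tabulate(seg$seeds[seg$seeds > 0], nbins = nlab),
      cell_area_px = tabulate(seg$cells[seg$cells > 0], nbins = nlab),
      tra_pixel_count = tra_tab$tra_pixel_count,
      tra_positive = tra_tab$tra_positive,
      cd45_mean = cd45_tab$cd45_mean
    )
  }
  list(
    cells = dplyr::bind_rows(recs),
    calibration = list(
      patient_id = patient_id,
      tra_threshold = thr,
      cd45_background = bg,
      n_control_fields = length(control_fields)
    )
  )
}
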