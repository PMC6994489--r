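#' Specification of one synthetic patient
#'
#' @param patient_id Unique identifier (used as directory name on disk).
#' @param group One of `"healthy"`, `"localized"`, `"metastatic"`,
#'   `"progressor"`.
#' @param n_fields Number of stained sample fields (at most 20, the maximum
#'   number of areas imaged per patient in the study design).
#' @param n_control_fields Number of secondary-antibody-only control fields
#'   (at most 10).
#' @param tra_fraction Per-patient probability that a cell is TRA-1-60
#'   positive.
#' @param cd45low_given_tra Probability that a TRA+ cell is CD45-low.
#' @param cells_per_field Mean number of cells per field; per-field counts
#'   are drawn Poisson around this mean.
#' @param tra_cd45_boost CD45 multiplier for this patient's TRA+ cells of
#'   the CD45-high class. Above 1 emulates the elevated CD45 observed on
#'   TRA+ cells of healthy donors; slightly below 1 emulates the overall
#'   lower CD45 of TRA+ cells in metastatic disease.
#' @param height_px,width_px Field raster size in pixels.
#' @param rng_seed Integer seed for this patient; every field derives its
#'   own child seed from it.
#' @return A one-row tibble (so patient specs stack into a design table).
#' @export
patient_spec <- function(patient_id, group,
                         n_fields = 14L, n_control_fields = 6L,
                         tra_fraction = 0, cd45low_given_tra = 0,
                         cells_per_field = 80,
                         tra_cd45_boost = 1.4,
                         height_px = 256L, width_px = 256L,
                         rng_seed = 1L) {
  group <- match.arg(group, c("healthy", "localized", "metastatic", "progressor"))
  stopifnot(
    n_fields >= 1, n_fields <= 20,
    n_control_fields >= 1, n_control_fields <= 10,
    tra_fraction >= 0, tra_fraction <= 1,
    cd45low_given_tra >= 0, cd45low_given_tra <= 1,
    cells_per_field > 0
  )
  tibble::tibble(
    patient_id = as.character(patient_id), group = group,
    n_fields = as.integer(n_fields),
    n_control_fields = as.integer(n_control_fields),
    tra_fraction = tra_fraction, cd45low_given_tra = cd45low_given_tra,
    cells_per_field = cells_per_field,
    tra_cd45_boost = tra_cd45_boost,
    height_px = as.integer(height_px), width_px = as.integer(width_px),
    rng_seed = as.integer(rng_seed)
  )
}

#' Default study-sized cohort design
#'
#' Builds a design table mirroring the published cohort structure: 17
#' healthy controls, 26 metastatic and 13 localized prostate cancer
#' patients, and 1 patient who progressed from localized to metastatic
#' disease (57 patients in total). Per-group TRA+ fractions are drawn from
#' the printed cohort ranges: healthy 0 to 2.3% (five donors with no TRA+
#' cells at all and most of the rest below 0.04%), metastatic 0.2% to
#' 13.6%, localized 0.002% to 3.1%. CD45-low TRA+ cells occur only in the
#' metastatic-like patients, in the progressor (targeting its printed 0.18
#' per 1000 rate), and — at a rate targeting ~0.04 per 1000 — in two of the
#' 13 localized patients.
#'
#' @param seed Master seed; deterministically spawns all per-patient seeds.
#' @param n_fields,n_control_fields,cells_per_field,height_px,width_px
#'   Scale parameters forwarded to every [patient_spec()].
#' @return A design tibble with one row per patient, usable with
#'   [generate_cohort()].
#' @export
cohort_design_paper <- function(seed = 1L,
                                n_fields = 14L, n_control_fields = 6L,
                                cells_per_field = 80,
                                height_px = 256L, width_px = 256L) {
  n_healthy <- 17L; n_met <- 26L; n_loc <- 13L
  n_total <- n_healthy + n_met + n_loc + 1L
  seeds <- spawn_seeds(seed, n_total + 1L)
  draw <- function(expr) with_local_seed(seeds[n_total + 1L], expr)

  # Healthy: 5 donors with zero TRA+ cells, 9 with trace levels (< 0.04%),
  # 3 in the upper printed range (0.6% - 2.3%, enough TRA+ cells at desk
  # scale that the CD45-difference measure retains healthy patients).
  healthy_p <- draw({
    c(
      rep(0, 5),
      exp(stats::runif(9, log(5e-5), log(4e-4))),
      exp(stats::runif(3, log(6e-3), log(2.3e-2)))
    )[sample.int(n_healthy)]
  })
  met_p <- draw(exp(stats::runif(n_met, log(2e-3), log(0.136))))
  met_q <- draw(stats::runif(n_met, 0.2, 0.5))
  loc_p <- draw(exp(stats::runif(n_loc, log(2e-5), log(0.031))))
  loc_q <- rep(0, n_loc)
  loc_pos <- draw(sample.int(n_loc, 2L))
  # Target ~0.04 CD45-low cells per 1000 cells in the two positive
  # localized patients: rate = 1000 * p * q.
  loc_q[loc_pos] <- pmin(1, 4e-5 / pmax(loc_p[loc_pos], 1e-6))

  rows <- list()
  add <- function(id, group, p, q, s, boost) {
    patient_spec(id, group,
      n_fields = n_fields, n_control_fields = n_control_fields,
      tra_fraction = p, cd45low_given_tra = q,
      cells_per_field = cells_per_field, tra_cd45_boost = boost,
      height_px = height_px, width_px = width_px, rng_seed = s
    )
  }
  # TRA+ cells carry elevated CD45 in healthy donors and localized disease
  # (boost 1.4) but trend below the leukocyte level in metastatic disease
  # and in the progressor (boost 0.9), reproducing the opposite signs of
  # the CD45 difference between the groups.
  k <- 0L
  for (i in seq_len(n_healthy)) {
    k <- k + 1L
    rows[[k]] <- add(sprintf("healthy_%02d", i), "healthy", healthy_p[i], 0, seeds[k], 1.4)
  }
  for (i in seq_len(n_met)) {
    k <- k + 1L
    rows[[k]] <- add(sprintf("metastatic_%02d", i), "metastatic", met_p[i], met_q[i], seeds[k], 0.9)
  }
  for (i in seq_len(n_loc)) {
    k <- k + 1L
    rows[[k]] <- add(sprintf("localized_%02d", i), "localized", loc_p[i], loc_q[i], seeds[k], 1.4)
  }
  k <- k + 1L
  rows[[k]] <- add("progressor_01", "progressor", 8e-3, 0.18 / (1000 * 8e-3), seeds[k], 0.9)
  dplyr::bind_rows(rows)
}

# Generate all fields of one patient in memory.
# Returns list(fields = list of tracell_field, controls = list of
# tracell_field, truth = per-cell truth tibble with field column).
generate_patient <- function(spec_row, params = intensity_params()) {
  s <- as.list(spec_row)
  if (!is.null(s$tra_cd45_boost)) params$tra_cd45_boost <- s$tra_cd45_boost
  field_seeds <- spawn_seeds(s$rng_seed, s$n_fields + s$n_control_fields + 1L)
  counts <- with_local_seed(
    field_seeds[s$n_fields + s$n_control_fields + 1L],
    pmax(1L, stats::rpois(s$n_fields + s$n_control_fields, s$cells_per_field))
  )
  # Cap the Poisson upper tail so a single crowded draw cannot push a field
  # past the packing density the placement sampler can realise.
  counts <- pmin(counts, as.integer(floor(s$cells_per_field + 3 * sqrt(s$cells_per_field))))
  fields <- vector("list", s$n_fields)
  truths <- vector("list", s$n_fields)
  for (i in seq_len(s$n_fields)) {
    fs <- field_spec(
      height_px = s$height_px, width_px = s$width_px,
      n_cells = counts[i],
      tra_fraction = s$tra_fraction,
      cd45low_given_tra = s$cd45low_given_tra,
      rng_seed = field_seeds[i]
    )
    out <- generate_field(fs, params)
    fields[[i]] <- out$field
    truths[[i]] <- dplyr::mutate(out$truth,
      patient_id = s$patient_id, field_index = i, .before = 1
    )
  }
  controls <- vector("list", s$n_control_fields)
  for (i in seq_len(s$n_control_fields)) {
    fs <- field_spec(
      height_px = s$height_px, width_px = s$width_px,
      n_cells = counts[s$n_fields + i],
      rng_seed = field_seeds[s$n_fields + i]
    )
    controls[[i]] <- generate_negative_control(fs, params)
  }
  list(
    fields = fields, controls = controls,
    truth = dplyr::bind_rows(truths)
  )
}

#' Generate a synthetic cohort on disk
#'
#' Renders every patient of a design to 16-bit grayscale TIFF files with the
#' layout `<out>/<patient_id>/field_01/{dapi,cd45,tra}.tif` (and
#' `control_01/...` for negative controls), and writes per-cell ground truth
#' (`cells_truth.csv`), per-patient truth (`patients_truth.csv`) and a
#' cohort manifest (`manifest.csv`) at the top level.
#'
#' @param design Design tibble, one row per patient (see [patient_spec()],
#'   [cohort_design_paper()]). Patient ids must be unique.
#' @param out_dir Output directory (created if missing).
#' @param params [intensity_params()] shared by all patients.
#' @return Invisibly, a list with `manifest`, `cells_truth` and
#'   `patients_truth` tibbles.
#' @export
generate_cohort <- function(design, out_dir, params = intensity_params()) {
  stopifnot(nrow(design) >= 1)
  if (anyDuplicated(design$patient_id)) {
    stop("duplicate patient identifiers in design: ",
         paste(unique(design$patient_id[duplicated(design$patient_id)]), collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truths <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    pat <- generate_patient(design[i, ], params)
    pdir <- file.path(out_dir, design$patient_id[i])
    for (j in seq_along(pat$fields)) {
      fdir <- file.path(pdir, sprintf("field_%02d", j))
      dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
      write_field_tiff(pat$fields[[j]], fdir)
    }
    for (j in seq_along(pat$controls)) {
      cdir <- file.path(pdir, sprintf("control_%02d", j))
      dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
      write_field_tiff(pat$controls[[j]], cdir)
    }
    truths[[i]] <- pat$truth
  }
  cells_truth <- dplyr::bind_rows(truths)
  patients_truth <- cells_truth |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_tra_pos = sum(.data$tra_positive),
      tra_fraction = mean(.data$tra_positive),
      n_cd45low = sum(.data$tra_positive & .data$cd45_class == "low"),
      cd45low_per_1000 = 1000 * .data$n_cd45low / .data$n_cells,
      .groups = "drop"
    ) |>
    dplyr::left_join(
      dplyr::select(design, "patient_id", "group"),
      by = "patient_id"
    )
  manifest <- dplyr::select(
    design, "patient_id", "group", "n_fields", "n_control_fields"
  )
  utils::write.csv(cells_truth, file.path(out_dir, "cells_truth.csv"), row.names = FALSE)
  utils::write.csv(patients_truth, file.path(out_dir, "patients_truth.csv"), row.names = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(list(
    manifest = manifest, cells_truth = cells_truth,
    patients_truth = patients_truth
  ))
}

#' Write one field's channels as 16-bit grayscale TIFFs
#'
#' @param field A `tracell_field`.
#' @param dir Directory that will receive `dapi.tif`, `cd45.tif`, `tra.tif`.
#' @return Invisibly, the directory.
#' @export
write_field_tiff <- function(field, dir) {
  for (ch in c("dapi", "cd45", "tra")) {
    tiff::writeTIFF(field[[ch]] / 65535, file.path(dir, paste0(ch, ".tif")),
                    bits.per.sample = 16L, compression = "none")
  }
  invisible(dir)
}

#' Read a grayscale TIFF as an integer intensity matrix
#'
#' @param path Path to an 8- or 16-bit single-channel TIFF.
#' @return An integer matrix of raw digital numbers.
#' @export
read_channel_tiff <- function(path) {
  x <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(x)) == 3) {
    if (dim(x)[3] != 1) stop("not a grayscale TIFF: ", path)
    x <- x[, , 1]
  }
  storage.mode(x) <- "integer"
  x
}

#' Read one field directory (dapi/cd45/tra TIFFs) as a `tracell_field`
#'
#' @param dir Directory containing `dapi.tif`, `cd45.tif`, `tra.tif`
#'   (controls may lack nothing: all three channels are always written).
#' @param pixel_size_um Physical pixel size to attach.
#' @return A `tracell_field`.
#' @export
read_field <- function(dir, pixel_size_um = 0.65) {
  chans <- lapply(
    stats::setNames(file.path(dir, c("dapi.tif", "cd45.tif", "tra.tif")),
                    c("dapi", "cd45", "tra")),
    read_channel_tiff
  )
  structure(
    c(chans, list(
      pixel_size_um = pixel_size_um,
      height_px = nrow(chans$dapi), width_px = ncol(chans$dapi)
    )),
    class = "tracell_field"
  )
}
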