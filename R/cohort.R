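#' Percentage of TRA+ cells per field
#'
#' Measurement 1: for each imaged field, the percentage of cells called
#' TRA-1-60 positive, summarised per patient by the mean and standard
#' deviation over fields. The spread is computed with the population
#' estimator (divisor n = number of fields) by default, matching a
#' "standard deviation from n fields" report; set
#' `cfg$sd_method = "sample"` for the n-1 estimator.
#'
#' @param records Per-cell records (see [quantify_patient()]), one or more
#'   patients.
#' @param cfg A [pipeline_config()].
#' @return A tibble with one row per patient: `patient_id`, `n_fields`,
#'   `mean_pct_tra`, `sd_pct_tra`, and a list-column `pct_tra_per_field`.
#' @export
percent_tra <- function(records, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  if (nrow(records) == 0) stop("no cell records supplied")
  sd_fun <- if (cfg$sd_method == "population") sd_pop else stats::sd
  records |>
    dplyr::group_by(.data$patient_id, .data$field_index) |>
    dplyr::summarise(pct = 100 * mean(.data$tra_positive), .groups = "drop_last") |>
    dplyr::summarise(
      n_fields = dplyr::n(),
      mean_pct_tra = mean(.data$pct),
      sd_pct_tra = sd_fun(.data$pct),
      pct_tra_per_field = list(.data$pct),
      .groups = "drop"
    )
}

#' Normalize CD45 levels by the patient's TRA-negative mean
#'
#' For each patient, the mean CD45 level over all TRA- cells defines the
#' normalization denominator; every cell's `cd45_norm` is its raw mean CD45
#' divided by that denominator, so TRA- cells average to exactly 1 and TRA+
#' cells are expressed relative to the normal leukocyte level.
#'
#' @param records Per-cell records for one or more patients.
#' @return `records` with a `cd45_norm` column added.
#' @export
normalize_cd45 <- function(records) {
  if (nrow(records) == 0) stop("no cell records supplied")
  records |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(df, key) {
      neg <- df$cd45_mean[!df$tra_positive]
      if (length(neg) == 0) {
        stop("patient ", key$patient_id, " has no TRA-negative cells; ",
             "cannot normalize CD45")
      }
      d <- mean(neg)
      if (d == 0) {
        stop("patient ", key$patient_id, " has zero mean TRA-negative CD45")
      }
      dplyr::mutate(df, cd45_norm = .data$cd45_mean / d)
    }) |>
    dplyr::ungroup()
}

#' TRA+/CD45-low cells per 1000 cells
#'
#' Measurement 2: counts cells that are TRA+ with normalized CD45 strictly
#' below `cfg$cd45low_cutoff`, expressed per 1000 analyzed cells.
#'
#' @param records Per-cell records with `cd45_norm` (see [normalize_cd45()]).
#' @param cfg A [pipeline_config()].
#' @return A tibble with `patient_id`, `n_cells`, `cd45low_count`,
#'   `cd45low_per_1000`.
#' @export
cd45low_per_1000 <- function(records, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  if (!"cd45_norm" %in% names(records)) {
    stop("records lack cd45_norm; run normalize_cd45() first")
  }
  records |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      cd45low_count = sum(.data$tra_positive &
                            .data$cd45_norm < cfg$cd45low_cutoff),
      cd45low_per_1000 = 1000 * .data$cd45low_count / .data$n_cells,
      .groups = "drop"
    )
}

#' Normalized CD45 difference between TRA+ and TRA- cells
#'
#' Measurement 3: mean normalized CD45 over TRA+ cells minus the mean over
#' TRA- cells (which is 1 by construction). Positive values mean TRA+
#' cells carry more CD45 than normal leukocytes (the healthy-donor
#' pattern); negative values mean less (the metastatic pattern). Patients
#' with fewer than `cfg$min_tra_cells_for_diff` TRA+ cells are excluded
#' (`cd45_diff = NA`, `included_in_diff = FALSE`).
#'
#' @inheritParams cd45low_per_1000
#' @return A tibble with `patient_id`, `n_tra_pos`, `cd45_diff`,
#'   `included_in_diff`.
#' @export
cd45_difference <- function(records, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  if (!"cd45_norm" %in% names(records)) {
    stop("records lack cd45_norm; run normalize_cd45() first")
  }
  records |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_tra_pos = sum(.data$tra_positive),
      cd45_diff = if (sum(.data$tra_positive) >= cfg$min_tra_cells_for_diff) {
        mean(.data$cd45_norm[.data$tra_positive]) -
          mean(.data$cd45_norm[!.data$tra_positive])
      } else {
        NA_real_
      },
      included_in_diff = sum(.data$tra_positive) >= cfg$min_tra_cells_for_diff,
      .groups = "drop"
    )
}

#' Summarise patients: all three measurements in one table
#'
#' Applies CD45 normalization and computes the three patient-level
#' measurements (per-field TRA+ percentage, TRA+/CD45-low per 1000 cells,
#' normalized CD45 difference) from per-cell records.
#'
#' @param records Per-cell records for one or more patients (cd45_norm is
#'   added internally if absent).
#' @param cfg A [pipeline_config()].
#' @param groups Optional tibble `patient_id`, `group` to join group labels.
#' @return A tibble with one row per patient.
#' @export
summarize_patients <- function(records, cfg = pipeline_config(), groups = NULL) {
  cfg <- as_config(cfg)
  if (!"cd45_norm" %in% names(records)) records <- normalize_cd45(records)
  out <- percent_tra(records, cfg) |>
    dplyr::left_join(cd45low_per_1000(records, cfg), by = "patient_id") |>
    dplyr::left_join(cd45_difference(records, cfg), by = "patient_id") |>
    dplyr::relocate("pct_tra_per_field", .after = dplyr::last_col())
  if (!is.null(groups)) {
    out <- dplyr::left_join(out, dplyr::distinct(groups[, c("patient_id", "group")]),
                            by = "patient_id") |>
      dplyr::relocate("group", .after = "patient_id")
  }
  out
}
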