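# Shared small fixtures. Everything is generated in code at test time.

# Configuration scaled to small test rasters: the default 50-px top-hat
# radius is appropriate for full fields but slow/degenerate on 64-px
# fixtures.
small_cfg <- function(...) {
  pipeline_config(bg_subtract_radius_px = 15L, ...)
}

tiny_field_spec <- function(n_cells = 12, seed = 1, ...) {
  field_spec(height_px = 128L, width_px = 128L, n_cells = n_cells,
             rng_seed = seed, ...)
}

# A small in-memory patient: returns list(fields, controls, truth).
tiny_patient <- function(seed = 1, n_fields = 2, n_controls = 2,
                         n_cells = 30, tra_fraction = 0.1,
                         cd45low_given_tra = 0, tra_cd45_boost = 1.4,
                         side = 160L) {
  spec <- patient_spec(
    paste0("p", seed), "metastatic",
    n_fields = n_fields, n_control_fields = n_controls,
    tra_fraction = tra_fraction, cd45low_given_tra = cd45low_given_tra,
    cells_per_field = n_cells, tra_cd45_boost = tra_cd45_boost,
    height_px = side, width_px = side, rng_seed = seed
  )
  tracell:::generate_patient(spec)
}

# Memoised default-scale cohort shared by the acceptance tests: generated
# and quantified once per test run.
.cohort_cache <- new.env(parent = emptyenv())

acceptance_cohort <- function(seed = 20260901) {
  key <- paste0("cohort_", seed)
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  design <- cohort_design_paper(seed = seed)
  cfg <- pipeline_config()
  cells <- list()
  truths <- list()
  calibs <- list()
  zero_control_violations <- 0L
  for (i in seq_len(nrow(design))) {
    pat <- tracell:::generate_patient(design[i, ])
    q <- quantify_patient(design$patient_id[i], pat$fields, pat$controls, cfg)
    cells[[i]] <- q$cells
    truths[[i]] <- pat$truth
    calibs[[i]] <- q$calibration
    # Re-run the calling rule on this patient's own controls.
    for (ctrl in pat$controls) {
      seg <- segment_field(ctrl, cfg)
      if (max(seg$cells) == 0) next
      calls <- call_tra(ctrl$tra, seg$cells, q$calibration$tra_threshold, cfg)
      zero_control_violations <- zero_control_violations + sum(calls$tra_positive)
    }
  }
  cells <- dplyr::bind_rows(cells)
  truth <- dplyr::bind_rows(truths)
  patients <- summarize_patients(
    normalize_cd45(cells), cfg,
    groups = design[, c("patient_id", "group")]
  )
  truth_patients <- truth |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(
      true_n = dplyr::n(),
      true_tra = sum(tra_positive),
      true_low = sum(tra_positive & cd45_class == "low"),
      .groups = "drop"
    )
  out <- list(
    design = design, cells = cells, truth = truth, patients = patients,
    truth_patients = truth_patients,
    calibrations = calibs,
    zero_control_violations = zero_control_violations
  )
  .cohort_cache[[key]] <- out
  out
}
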