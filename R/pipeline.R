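#' Discover a cohort directory as a study manifest
#'
#' Walks the directory-convention layout written by [generate_cohort()]
#' (`<dir>/<patient>/field_XX/{dapi,cd45,tra}.tif`,
#' `<dir>/<patient>/control_XX/...`). Group labels are joined from
#' `manifest.csv` when present, otherwise set to `NA`.
#'
#' @param dir Cohort root directory.
#' @return A tibble with one row per patient: `patient_id`, `group`, and
#'   list-columns `field_dirs`, `control_dirs`.
#' @export
discover_cohort <- function(dir) {
  if (!dir.exists(dir)) stop("cohort directory not found: ", dir)
  pats <- list.dirs(dir, recursive = FALSE)
  pats <- pats[vapply(pats, function(p) {
    length(list.dirs(p, recursive = FALSE)) > 0
  }, logical(1))]
  if (length(pats) == 0) stop("no patient directories found under ", dir)
  man <- tibble::tibble(
    patient_id = basename(pats),
    group = NA_character_,
    field_dirs = lapply(pats, function(p) {
      sort(list.dirs(p, recursive = FALSE)[grepl("/field_", list.dirs(p, recursive = FALSE))])
    }),
    control_dirs = lapply(pats, function(p) {
      sort(list.dirs(p, recursive = FALSE)[grepl("/control_", list.dirs(p, recursive = FALSE))])
    })
  )
  mpath <- file.path(dir, "manifest.csv")
  if (file.exists(mpath)) {
    gm <- utils::read.csv(mpath, stringsAsFactors = FALSE)
    man$group <- gm$group[match(man$patient_id, gm$patient_id)]
  }
  if (anyDuplicated(man$patient_id)) stop("duplicate patient ids in cohort")
  man
}

read_field_checked <- function(fdir, log) {
  paths <- file.path(fdir, c("dapi.tif", "cd45.tif", "tra.tif"))
  missing <- !file.exists(paths)
  if (any(missing)) {
    log("warning", sprintf(
      "skipping field %s: missing channel(s) %s", fdir,
      paste(c("dapi", "cd45", "tra")[missing], collapse = ", ")
    ))
    return(NULL)
  }
  read_field(fdir)
}

#' Run the full analysis pipeline over a cohort directory
#'
#' For every patient: segments the negative controls, calibrates the
#' TRA-1-60 threshold and CD45 background, segments the sample fields,
#' calls TRA+ cells and measures CD45, then computes the three
#' patient-level measurements and the between-group ROC comparisons.
#' Outputs are written incrementally to `out_dir`: `cells.csv`,
#' `patients.csv`, `roc.csv`, `calibration.json`, optional QC overlay PNGs,
#' and a run log. Fields with missing channels are skipped with a logged
#' warning; patients without a usable control are excluded with a logged
#' error. The run is deterministic given inputs and configuration.
#'
#' @param input_dir Cohort root directory (layout of [generate_cohort()]).
#' @param out_dir Output directory (created if missing).
#' @param cfg A [pipeline_config()].
#' @param plan Comparison plan for [run_comparisons()]; comparisons whose
#'   groups are absent from the cohort are skipped with a warning.
#' @param overlays If `TRUE`, writes one QC overlay PNG per analyzed field.
#' @return Invisibly, a list with `cells`, `patients`, `roc`,
#'   `calibrations`.
#' @export
run_pipeline <- function(input_dir, out_dir, cfg = pipeline_config(),
                         plan = default_comparison_plan(),
                         overlays = FALSE) {
  cfg <- as_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  log <- function(level, msg) {
    line <- sprintf("[%s] %s", toupper(level), msg)
    message(line)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
  }
  cat(sprintf("tracell %s run started %s\n",
              as.character(utils::packageVersion("tracell")),
              format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      file = log_path)
  cat("configuration:\n", file = log_path, append = TRUE)
  for (nm in names(cfg)) {
    cat(sprintf("  %s: %s\n", nm, format(cfg[[nm]])), file = log_path, append = TRUE)
  }

  man <- discover_cohort(input_dir)
  cells_all <- list()
  calibs <- list()
  for (i in seq_len(nrow(man))) {
    pid <- man$patient_id[i]
    controls <- Filter(Negate(is.null),
                       lapply(man$control_dirs[[i]], read_field_checked, log = log))
    if (length(controls) == 0) {
      log("error", sprintf("patient %s excluded: no usable control fields", pid))
      next
    }
    fields <- Filter(Negate(is.null),
                     lapply(man$field_dirs[[i]], read_field_checked, log = log))
    if (length(fields) == 0) {
      log("error", sprintf("patient %s excluded: no usable sample fields", pid))
      next
    }
    q <- quantify_patient(pid, fields, controls, cfg)
    cells_all[[pid]] <- q$cells
    calibs[[pid]] <- q$calibration
    log("info", sprintf(
      "patient %s: %d cells, %d TRA+, threshold %.1f DN, CD45 background %.2f DN",
      pid, nrow(q$cells), sum(q$cells$tra_positive),
      q$calibration$tra_threshold, q$calibration$cd45_background
    ))
    if (overlays) {
      for (j in seq_along(fields)) {
        seg <- segment_field(fields[[j]], cfg)
        calls <- call_tra(fields[[j]]$tra, seg$cells,
                          q$calibration$tra_threshold, cfg)
        write_qc_overlay(
          fields[[j]], seg, calls,
          file.path(out_dir, sprintf("overlay_%s_field_%02d.png", pid, j))
        )
      }
    }
  }
  if (length(cells_all) == 0) stop("no patients could be analyzed")
  cells <- dplyr::bind_rows(cells_all)
  cells <- normalize_cd45(cells)
  patients <- summarize_patients(cells, cfg, groups = man)

  present <- unique(stats::na.omit(patients$group))
  plan_ok <- plan[plan$group_a %in% present & plan$group_b %in% present, , drop = FALSE]
  if (nrow(plan_ok) < nrow(plan)) {
    log("warning", sprintf("skipping %d comparison(s) with absent groups",
                           nrow(plan) - nrow(plan_ok)))
  }
  roc_rows <- lapply(seq_len(nrow(plan_ok)), function(i) {
    tryCatch(
      run_comparisons(patients, plan_ok[i, ], cfg),
      error = function(e) {
        log("warning", sprintf(
          "comparison %s: %s vs %s skipped: %s",
          plan_ok$measure[i], plan_ok$group_a[i], plan_ok$group_b[i],
          conditionMessage(e)
        ))
        NULL
      }
    )
  })
  roc_tab <- dplyr::bind_rows(roc_rows)

  utils::write.csv(cells, file.path(out_dir, "cells.csv"), row.names = FALSE)
  patients_out <- patients
  patients_out$pct_tra_per_field <- vapply(
    patients$pct_tra_per_field,
    function(v) paste(sprintf("%.10g", v), collapse = ";"), character(1)
  )
  utils::write.csv(patients_out, file.path(out_dir, "patients.csv"),
                   row.names = FALSE, na = "")
  if (nrow(roc_tab) > 0) {
    utils::write.csv(roc_tab[, setdiff(names(roc_tab), "roc")],
                     file.path(out_dir, "roc.csv"), row.names = FALSE)
  } else {
    utils::write.csv(tibble::tibble(), file.path(out_dir, "roc.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(calibs, file.path(out_dir, "calibration.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log("info", sprintf("run complete: %d patients, %d cells",
                      nrow(patients), nrow(cells)))
  invisible(list(cells = cells, patients = patients, roc = roc_tab,
                 calibrations = calibs))
}

#' Write a QC overlay image for one field
#'
#' Renders the DAPI channel in grayscale with nucleus outlines in green and
#' a yellow circle around every TRA+ cell, mirroring the software-validation
#' display of the original analysis.
#'
#' @param field A `tracell_field`.
#' @param seg Output of [segment_field()] for that field.
#' @param calls Output of [call_tra()].
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_qc_overlay <- function(field, seg, calls, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the png package is required for QC overlays")
  }
  dapi <- field$dapi
  g <- dapi / max(max(dapi), 1)
  h <- nrow(g); w <- ncol(g)
  rgb <- array(rep(g, 3), dim = c(h, w, 3))

  seeds <- unclass_labels(seg$seeds)
  edge <- matrix(FALSE, h, w)
  edge[-1, ] <- edge[-1, ] | (seeds[-1, ] != seeds[-h, ])
  edge[, -1] <- edge[, -1] | (seeds[, -1] != seeds[, -w])
  edge <- edge & seeds > 0
  rgb[, , 1][edge] <- 0
  rgb[, , 2][edge] <- 1
  rgb[, , 3][edge] <- 0

  pos <- calls$cell_label[calls$tra_positive]
  if (length(pos) > 0) {
    cells <- unclass_labels(seg$cells)
    for (id in pos) {
      idx <- which(cells == id)
      rr <- (idx - 1L) %% h + 1L
      cc <- (idx - 1L) %/% h + 1L
      r0 <- mean(rr); c0 <- mean(cc)
      rad <- sqrt(length(idx) / pi) + 2
      theta <- seq(0, 2 * pi, length.out = 120)
      pr <- pmin(pmax(round(r0 + rad * sin(theta)), 1), h)
      pc <- pmin(pmax(round(c0 + rad * cos(theta)), 1), w)
      for (k in seq_along(pr)) {
        rgb[pr[k], pc[k], 1] <- 1
        rgb[pr[k], pc[k], 2] <- 1
        rgb[pr[k], pc[k], 3] <- 0
      }
    }
  }
  png::writePNG(rgb, path)
  invisible(path)
}
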