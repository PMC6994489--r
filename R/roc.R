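#' ROC analysis of a patient-level measure
#'
#' Computes the ROC curve and its area for a continuous score separating
#' two groups. The AUC is computed by the Wilcoxon-Mann-Whitney identity
#' (ties counted one half); the curve is oriented so that AUC >= 0.5. The
#' confidence interval uses the Hanley-McNeil standard error with a normal
#' approximation (clipped to [0, 1]) by default, or the DeLong variance
#' with `cfg$roc_ci = "delong"`. The p-value is a two-sided normal test of
#' AUC = 0.5 using the same standard error. No multiple-testing correction
#' is applied across comparisons.
#'
#' @param scores Numeric vector of scores (finite).
#' @param positive Logical vector: `TRUE` for the positive group.
#' @param cfg A [pipeline_config()].
#' @param conf_level Confidence level of the interval.
#' @return An object of class `tracell_roc`: a list with `auc`, `se`,
#'   `ci_low`, `ci_high`, `p_value`, `n_pos`, `n_neg`, `flipped` (whether
#'   orientation was reversed so AUC >= 0.5), and `curve` (a tibble of
#'   `fpr`, `tpr`).
#' @examples
#' r <- roc_analysis(c(1, 2, 3, 4, 5, 6), c(rep(FALSE, 3), rep(TRUE, 3)))
#' r$auc
#' @export
roc_analysis <- function(scores, positive, cfg = pipeline_config(),
                         conf_level = 0.95) {
  cfg <- as_config(cfg)
  stopifnot(length(scores) == length(positive))
  positive <- as.logical(positive)
  keep <- !is.na(scores) & !is.na(positive)
  scores <- scores[keep]; positive <- positive[keep]
  if (any(!is.finite(scores))) stop("scores must be finite")
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) stop("both groups must be non-empty")

  auc <- auc_mann_whitney(scores[positive], scores[!positive])
  flipped <- auc < 0.5
  if (flipped) {
    scores <- -scores
    auc <- 1 - auc
  }

  if (cfg$roc_ci == "delong") {
    se <- sqrt(delong_variance(scores[positive], scores[!positive]))
  } else {
    se <- hanley_mcneil_se(auc, n_pos, n_neg)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci_low <- max(0, auc - z * se)
  ci_high <- min(1, auc + z * se)
  p_value <- if (se == 0) {
    if (auc == 0.5) 1 else 0
  } else {
    2 * stats::pnorm(-abs(auc - 0.5) / se)
  }

  structure(
    list(
      auc = auc, se = se, ci_low = ci_low, ci_high = ci_high,
      p_value = p_value, n_pos = n_pos, n_neg = n_neg,
      flipped = flipped, conf_level = conf_level,
      method = cfg$roc_ci,
      curve = roc_curve_points(scores, positive)
    ),
    class = "tracell_roc"
  )
}

# AUC by the Mann-Whitney identity with mid-ranks (ties = 1/2).
auc_mann_whitney <- function(pos, neg) {
  n_pos <- length(pos); n_neg <- length(neg)
  r <- rank(c(pos, neg))
  (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Hanley & McNeil (1982) standard error of the AUC.
hanley_mcneil_se <- function(a, n_pos, n_neg) {
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  sqrt((a * (1 - a) + (n_pos - 1) * (q1 - a^2) + (n_neg - 1) * (q2 - a^2)) /
         (n_pos * n_neg))
}

# DeLong variance of the AUC via placement values.
delong_variance <- function(pos, neg) {
  m <- length(pos); n <- length(neg)
  v10 <- vapply(pos, function(x) (sum(x > neg) + 0.5 * sum(x == neg)) / n,
                numeric(1))
  v01 <- vapply(neg, function(y) (sum(pos > y) + 0.5 * sum(pos == y)) / m,
                numeric(1))
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  s10 / m + s01 / n
}

# Stepwise ROC curve from (0,0) to (1,1), thresholds descending.
roc_curve_points <- function(scores, positive) {
  n_pos <- sum(positive); n_neg <- sum(!positive)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(positive & scores >= t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(!positive & scores >= t) / n_neg, numeric(1))
  tibble::tibble(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
}

#' @export
print.tracell_roc <- function(x, ...) {
  cat(sprintf(
    "<tracell ROC> AUC %.3f (%.0f%% CI %.3f-%.3f), p = %.3g, n = %d vs %d (%s)\n",
    x$auc, 100 * x$conf_level, x$ci_low, x$ci_high, x$p_value,
    x$n_pos, x$n_neg, x$method
  ))
  invisible(x)
}

#' Tidy a tracell ROC object into curve points
#'
#' @param x A `tracell_roc`.
#' @param ... Unused.
#' @return A tibble of `fpr`, `tpr` curve points.
#' @method tidy tracell_roc
#' @export
tidy.tracell_roc <- function(x, ...) x$curve

#' One-row summary of a tracell ROC object
#'
#' @param x A `tracell_roc`.
#' @param ... Unused.
#' @return A one-row tibble: `auc`, `se`, `ci_low`, `ci_high`, `p_value`,
#'   `n_pos`, `n_neg`.
#' @method glance tracell_roc
#' @export
glance.tracell_roc <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, se = x$se, ci_low = x$ci_low, ci_high = x$ci_high,
    p_value = x$p_value, n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' Plot a tracell ROC curve
#'
#' @param object A `tracell_roc`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tracell_roc
#' @export
autoplot.tracell_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False-positive rate", y = "True-positive rate",
      title = sprintf("AUC = %.2f (%.0f%% CI %.2f-%.2f)",
                      object$auc, 100 * object$conf_level,
                      object$ci_low, object$ci_high)
    ) +
    ggplot2::theme_minimal()
}

#' Default comparison plan
#'
#' The five between-group comparisons reported by the study: the mean TRA+
#' percentage (measure 1) for healthy vs metastatic and localized vs
#' metastatic, and the normalized CD45 difference (measure 3) for healthy
#' vs metastatic, localized vs metastatic and healthy vs localized.
#'
#' @return A tibble with columns `measure`, `group_a`, `group_b`.
#' @export
default_comparison_plan <- function() {
  tibble::tribble(
    ~measure,            ~group_a,    ~group_b,
    "mean_pct_tra",      "healthy",   "metastatic",
    "mean_pct_tra",      "localized", "metastatic",
    "cd45_diff",         "healthy",   "metastatic",
    "cd45_diff",         "localized", "metastatic",
    "cd45_diff",         "healthy",   "localized"
  )
}

#' Run a plan of between-group ROC comparisons
#'
#' For every row of the plan, runs [roc_analysis()] of the named
#' patient-level measure between the two groups, with `group_b` as the
#' positive class. For the CD45-difference measure, only patients included
#' in that measure (at least `cfg$min_tra_cells_for_diff` TRA+ cells)
#' enter, and each group must retain at least 2 included patients.
#'
#' @param summaries Patient summary table from [summarize_patients()] with a
#'   `group` column.
#' @param plan Comparison plan tibble (`measure`, `group_a`, `group_b`);
#'   defaults to [default_comparison_plan()].
#' @param cfg A [pipeline_config()].
#' @return A tibble with one row per comparison: plan columns, `auc`, `se`,
#'   `ci_low`, `ci_high`, `p_value`, `n_a`, `n_b`, and a list-column `roc`
#'   holding the full `tracell_roc` objects.
#' @export
run_comparisons <- function(summaries, plan = default_comparison_plan(),
                            cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  if (!"group" %in% names(summaries)) stop("summaries must have a group column")
  purrr::pmap_dfr(plan, function(measure, group_a, group_b) {
    sub <- summaries[summaries$group %in% c(group_a, group_b), , drop = FALSE]
    if (!measure %in% names(sub)) stop("unknown measure: ", measure)
    if (measure == "cd45_diff") {
      sub <- sub[sub$included_in_diff, , drop = FALSE]
      for (g in c(group_a, group_b)) {
        if (sum(sub$group == g) < 2) {
          stop("group ", g, " has fewer than 2 patients included in the ",
               "CD45-difference measure")
        }
      }
    }
    if (!any(sub$group == group_a) || !any(sub$group == group_b)) {
      stop("empty group in comparison ", group_a, " vs ", group_b)
    }
    r <- roc_analysis(sub[[measure]], sub$group == group_b, cfg)
    tibble::tibble(
      measure = measure, group_a = group_a, group_b = group_b,
      auc = r$auc, se = r$se, ci_low = r$ci_low, ci_high = r$ci_high,
      p_value = r$p_value,
      n_a = sum(sub$group == group_a), n_b = sum(sub$group == group_b),
      roc = list(r)
    )
  })
}

#' Plot all comparisons of a ROC table
#'
#' @param comparisons Output of [run_comparisons()].
#' @return A ggplot object with one facet per comparison.
#' @export
plot_comparisons <- function(comparisons) {
  curves <- purrr::pmap_dfr(
    comparisons[, c("measure", "group_a", "group_b", "auc", "roc")],
    function(measure, group_a, group_b, auc, roc) {
      dplyr::mutate(roc$curve,
        comparison = sprintf("%s: %s vs %s (AUC %.2f)",
                             measure, group_a, group_b, auc)
      )
    }
  )
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::facet_wrap(~comparison) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate") +
    ggplot2::theme_minimal()
}
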