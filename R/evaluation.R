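#' Per-region correlation between model predictions and LSmeans
#'
#' Quantifies prediction precision: within every region, the Pearson
#' correlation between the model's predicted weight at each household's
#' environmental covariates and that household's least-squares mean (the
#' observed value). Regions need more than 25 households for a reliable
#' correlation estimate (Bonett-Wright sample-size rule); smaller regions
#' are reported but flagged ungated and never enter summaries. The
#' large-sample standard error `se_r = (1 - r^2) / sqrt(n - 1)` accompanies
#' every estimate. Correlations are in-sample (the same households used for
#' fitting), so out-of-sample precision may be lower.
#'
#' @param fit A [boost_gam()] fit.
#' @param lsmeans Tibble from [lsmeans_at_week()] (needs `household_id`,
#'   `region`, `lsmean`).
#' @param covariates Tibble from [extract_covariates()] with one row per
#'   household.
#' @param gate_n Minimum household count (strict) for gating (default 25).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param m Boosting iteration at which to predict (default: the fit's).
#' @return A tibble of class `correlation_report`: `region`, `n`, `r`,
#'   `se_r`, `gated`. Regions with fewer than 3 households get `NA`
#'   correlations.
#' @export
predicted_vs_lsmeans <- function(fit, lsmeans, covariates, gate_n = 25,
                                 method = c("pearson", "spearman"),
                                 m = fit$m_stop) {
  method <- match.arg(method)
  check_columns(lsmeans, c("household_id", "region", "lsmean"), "`lsmeans`")
  check_columns(covariates, c("household_id", fit$vars), "`covariates`")
  d <- lsmeans |>
    inner_join(covariates, by = "household_id")
  if (nrow(d) < nrow(lsmeans)) {
    abort("some LSmeans households have no covariate row", class = "pdmboost_schema_error")
  }
  d$predicted <- predict(fit, d[fit$vars], m = m)
  out <- d |>
    group_by(.data$region) |>
    summarise(
      n = dplyr::n(),
      r = if (dplyr::n() >= 3) suppressWarnings(
        cor(.data$predicted, .data$lsmean, method = method)) else NA_real_,
      .groups = "drop"
    ) |>
    mutate(
      se_r = (1 - .data$r^2) / sqrt(.data$n - 1),
      gated = .data$n > gate_n
    ) |>
    arrange(.data$region)
  structure(out, class = c("correlation_report", class(tibble())),
            method = method, gate_n = gate_n)
}

#' Summarize a correlation report over its gated regions
#'
#' Median, minimum and maximum correlation over the regions that pass the
#' sample-size gate (n strictly greater than the gate). Ungated regions
#' never contribute.
#'
#' @param report A [predicted_vs_lsmeans()] report.
#' @return A one-row tibble: `n_regions`, `median_r`, `min_r`, `max_r`;
#'   zero rows (with a warning) when no region is gated.
#' @export
summarize_report <- function(report) {
  check_columns(report, c("region", "n", "r", "gated"), "`report`")
  g <- report[report$gated & !is.na(report$r), ]
  if (nrow(g) == 0) {
    warn("no gated regions: empty summary")
    return(tibble(n_regions = integer(), median_r = numeric(),
                  min_r = numeric(), max_r = numeric()))
  }
  tibble(
    n_regions = nrow(g),
    median_r = median(g$r),
    min_r = min(g$r),
    max_r = max(g$r)
  )
}

#' @method autoplot correlation_report
#' @export
autoplot.correlation_report <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$region, .data$r, alpha = .data$gated)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$r - .data$se_r,
                                        ymax = .data$r + .data$se_r),
                           width = 0.2) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                name = "n > gate") +
    ggplot2::labs(x = NULL, y = "correlation (predicted vs LSmeans)")
}
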