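# Household growth model: common intercept, household-specific week slope.
#
# y_hw = b0 + s_h * w + e. The design is an "arrow" matrix (one dense
# intercept column plus a block-diagonal slope column per household), so the
# normal equations are solved exactly by a Schur complement on the intercept
# instead of forming the full design: with t_h = sum of weeks and
# d_h = sum of squared weeks in household h,
#   b0  = (sum y - sum_h t_h Swy_h / d_h) / (n - sum_h t_h^2 / d_h)
#   s_h = (Swy_h - t_h b0) / d_h
# and the (b0, s_h) covariance entries follow from the blockwise inverse.

#' Fit the common-intercept, household-slope growth model
#'
#' Ordinary least squares of average individual weight on week, with a single
#' intercept shared by every household of a breed-phase dataset (all
#' chickens of a breed assumed to weigh the same at hatching) and a separate
#' linear growth rate per household. Weeks enter as a continuous covariate.
#' Duplicated observations count twice, exactly as in weighted least
#' squares. Designs in which intercept and slope are confounded (all
#' observations at a single identical week) raise a rank-deficiency error.
#'
#' @param records Tibble with columns `household_id`, `week`, `avg_weight_g`
#'   (plus optional `breed`, `sex`, `region`, carried through). Must contain
#'   a single breed and phase; fit breed-phase datasets independently.
#' @return An object of class `household_growth_fit`: common intercept, a
#'   per-household tibble of slopes (with carried metadata), the residual
#'   variance (denominator `n - (1 + n_households)`, floored at 1), and the
#'   quantities needed for standard errors.
#' @seealso [lsmeans_at_week()]
#' @export
fit_household_growth <- function(records) {
  check_columns(records, c("household_id", "week", "avg_weight_g"), "`records`")
  if (nrow(records) < 2) abort_invalid("need at least 2 observations")
  if ("breed" %in% names(records) && length(unique(records$breed)) > 1) {
    abort_invalid("`records` spans multiple breeds; fit each breed separately")
  }

  sums <- records |>
    group_by(.data$household_id) |>
    summarise(
      n = dplyr::n(),
      t = sum(.data$week),
      d = sum(.data$week^2),
      swy = sum(.data$week * .data$avg_weight_g),
      sy = sum(.data$avg_weight_g),
      .groups = "drop"
    )
  n_obs <- nrow(records)
  H <- nrow(sums)
  if (any(sums$d <= 0)) {
    abort("household with non-positive sum of squared weeks", class = "pdmboost_data_error")
  }
  q <- n_obs - sum(sums$t^2 / sums$d)
  if (q / n_obs < 1e-10) {
    abort(paste("intercept and slopes are confounded (all observations at a",
                "single week); the design is rank deficient"),
          class = "pdmboost_rank_deficiency")
  }
  b0 <- (sum(sums$sy) - sum(sums$t * sums$swy / sums$d)) / q
  slopes <- (sums$swy - sums$t * b0) / sums$d

  fitted <- b0 + slopes[match(records$household_id, sums$household_id)] * records$week
  rss <- sum((records$avg_weight_g - fitted)^2)
  df <- max(1, n_obs - (1 + H))
  sigma2 <- rss / df

  meta_cols <- intersect(c("breed", "sex", "region", "lon", "lat"), names(records))
  meta <- records |>
    select(dplyr::all_of(c("household_id", meta_cols))) |>
    distinct(.data$household_id, .keep_all = TRUE)
  per_household <- sums |>
    mutate(slope = slopes,
           # blockwise-inverse covariance pieces (unit-variance scale)
           var_slope_u = 1 / .data$d + .data$t^2 / (.data$d^2 * q),
           cov_b0_slope_u = -.data$t / (.data$d * q)) |>
    select("household_id", "n", "slope", "var_slope_u", "cov_b0_slope_u") |>
    left_join(meta, by = "household_id")

  structure(
    list(common_intercept = b0,
         households = per_household,
         residual_variance = sigma2,
         var_b0_u = 1 / q,
         rss = rss, df = df,
         n_obs = n_obs, n_households = H,
         design_rank = 1 + H),
    class = "household_growth_fit"
  )
}

#' Least-squares means per household at an evaluation week
#'
#' Evaluates `lsmean_h = b0 + s_h * week` with its standard error from the
#' estimated covariance of `(b0, s_h)`, for every household of the fit.
#' Using the phase-average week as `eval_week` standardizes households
#' weighed at different ages to a common footing; the LSmeans are the
#' response values of the downstream phenotype distribution model.
#'
#' @param fit A [fit_household_growth()] fit.
#' @param eval_week Week at which to evaluate (finite scalar), typically
#'   [phase_average_week()] of the phase dataset.
#' @param phase Optional phase name carried into the output.
#' @return A tibble: `household_id`, carried metadata (`breed`, `sex`,
#'   `region`, ... when present), `phase`, `eval_week`, `lsmean` (g), `se`
#'   (g).
#' @export
lsmeans_at_week <- function(fit, eval_week, phase = NA_character_) {
  stopifnot(inherits(fit, "household_growth_fit"))
  if (!is.numeric(eval_week) || length(eval_week) != 1 || !is.finite(eval_week)) {
    abort_invalid("`eval_week` must be a finite scalar")
  }
  hh <- fit$households
  var_u <- fit$var_b0_u + eval_week^2 * hh$var_slope_u +
    2 * eval_week * hh$cov_b0_slope_u
  out <- hh |>
    mutate(
      phase = phase,
      eval_week = eval_week,
      lsmean = fit$common_intercept + .data$slope * eval_week,
      se = sqrt(pmax(0, fit$residual_variance * var_u))
    ) |>
    select(-"var_slope_u", -"cov_b0_slope_u", -"n", -"slope")
  meta_first <- intersect(c("household_id", "breed", "sex", "region", "lon", "lat"),
                          names(out))
  out |> select(dplyr::all_of(meta_first), "phase", "eval_week", "lsmean", "se")
}

#' @export
print.household_growth_fit <- function(x, ...) {
  cat(sprintf("Household growth fit: common intercept %.2f g, %d households, %d obs\n",
              x$common_intercept, x$n_households, x$n_obs))
  cat(sprintf("  residual variance %.3f g² (df = %d)\n", x$residual_variance, x$df))
  invisible(x)
}

#' @describeIn fit_household_growth `tidy()` method: per-household slopes.
#' @param x A `household_growth_fit` (for `tidy`/`glance`).
#' @param ... Unused.
#' @method tidy household_growth_fit
#' @export
tidy.household_growth_fit <- function(x, ...) {
  x$households |>
    mutate(slope_se = sqrt(x$residual_variance * .data$var_slope_u)) |>
    select(-"var_slope_u", -"cov_b0_slope_u")
}

#' @describeIn fit_household_growth `glance()` method: one-row fit summary.
#' @method glance household_growth_fit
#' @export
glance.household_growth_fit <- function(x, ...) {
  tibble(
    common_intercept = x$common_intercept,
    residual_variance = x$residual_variance,
    nobs = x$n_obs,
    n_households = x$n_households,
    design_rank = x$design_rank,
    df_residual = x$df
  )
}
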