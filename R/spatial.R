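#' Mask grid cells outside the training environmental range
#'
#' A cell is masked `out_of_range` when ANY model covariate's value at that
#' cell lies strictly outside the closed interval `[training min, training
#' max]` of that covariate; `nodata` cells keep their own reason. This is the
#' conservative reading of excluding areas whose environmental conditions
#' lie outside the range in which the animals were tested (e.g. deserts):
#' the model is never asked to extrapolate onto such cells. The mask is
#' computed from the model's own training rows, so each independently fitted
#' model carries its own support.
#'
#' @param stack An `env_stack` whose layers include every training
#'   covariate.
#' @param training Data frame of training covariate rows (e.g.
#'   [extract_covariates()] restricted to the model's households); columns
#'   other than stack layers are ignored, but every used layer must be
#'   present.
#' @param vars Covariates to check (default: all stack layers present in
#'   `training`).
#' @return A character matrix (same shape as the grid) of class `env_mask`
#'   with entries `"ok"`, `"nodata"` or `"out_of_range"`; the per-variable
#'   training ranges are attached as attribute `"ranges"`.
#' @export
env_range_mask <- function(stack, training, vars = NULL) {
  stopifnot(inherits(stack, "env_stack"))
  vars <- vars %||% intersect(stack$var_names, names(training))
  if (length(vars) == 0) abort("no shared covariates between stack and training data",
                               class = "pdmboost_schema_error")
  missing <- setdiff(vars, stack$var_names)
  if (length(missing)) {
    abort(sprintf("stack is missing layer(s): %s", paste(missing, collapse = ", ")),
          class = "pdmboost_schema_error")
  }
  check_columns(training, vars, "`training`")

  out <- matrix("ok", nrow = dim(stack$values)[1], ncol = dim(stack$values)[2])
  ranges <- matrix(NA_real_, nrow = length(vars), ncol = 2,
                   dimnames = list(vars, c("min", "max")))
  oor <- matrix(FALSE, nrow(out), ncol(out))
  for (v in vars) {
    j <- match(v, stack$var_names)
    rng <- range(training[[v]])
    ranges[v, ] <- rng
    layer <- stack$values[, , j]
    oor <- oor | layer < rng[1] | layer > rng[2]
  }
  out[oor] <- "out_of_range"
  out[stack$nodata] <- "nodata"
  structure(out, class = c("env_mask", "matrix", "array"), ranges = ranges)
}

#' Predict body weight over the environmental grid
#'
#' Applies a boosted phenotype distribution model cellwise to every unmasked
#' cell of the stack; masked cells (nodata or outside the training
#' environmental range) carry no prediction.
#'
#' @param fit A [boost_gam()] fit.
#' @param stack The `env_stack` to predict on.
#' @param mask An [env_range_mask()] for the same stack; defaults to the
#'   mask computed from the fit's own training covariates.
#' @param m Boosting iteration at which to predict (default: the fit's).
#' @param breed,sex,phase Optional labels carried on the surface.
#' @return A tibble of class `prediction_surface`: `row`, `col`, `lon`,
#'   `lat`, `region`, `mask_reason`, `predicted` (grams; `NA` where masked),
#'   with the model's covariate names attached as attribute `"vars"`.
#' @export
predict_surface <- function(fit, stack, mask = NULL, m = fit$m_stop,
                            breed = NA_character_, sex = NA_character_,
                            phase = NA_character_) {
  stopifnot(inherits(fit, "boost_fit"), inherits(stack, "env_stack"))
  if (is.null(mask)) mask <- env_range_mask(stack, fit$data[fit$vars])
  cells <- as_tibble(stack)
  reason <- mask[cbind(cells$row, cells$col)]
  cells$mask_reason <- reason
  cells$predicted <- NA_real_
  ok <- reason == "ok"
  if (any(ok)) {
    cells$predicted[ok] <- predict(fit, cells[ok, fit$vars], m = m)
  }
  out <- cells |>
    select("row", "col", "lon", "lat", "region", "mask_reason", "predicted")
  structure(out,
            class = c("prediction_surface", class(tibble())),
            vars = fit$vars, breed = breed, sex = sex, phase = phase, m = m)
}

#' Rank regions by predicted body weight
#'
#' Summarizes the unmasked cells of a prediction surface per region
#' (default: the mean predicted weight) and flags the best region. Regions
#' with every cell masked are excluded from the ranking. Ties on the summary
#' are resolved alphabetically and flagged.
#'
#' @param surface A [predict_surface()] result.
#' @param statistic `"mean"` (default), `"median"` or `"max"`.
#' @return A tibble: `region`, `n_cells`, `value` (grams), `best` (logical),
#'   `tied` (logical), plus the statistic name as attribute `"statistic"`.
#' @export
region_suitability <- function(surface, statistic = c("mean", "median", "max")) {
  statistic <- match.arg(statistic)
  fun <- switch(statistic, mean = mean, median = stats::median, max = max)
  ok <- surface[surface$mask_reason == "ok" & !is.na(surface$predicted), ]
  if (nrow(ok) == 0) {
    abort("every cell is masked; no region can be ranked",
          class = "pdmboost_empty_result")
  }
  out <- ok |>
    group_by(.data$region) |>
    summarise(n_cells = dplyr::n(), value = fun(.data$predicted),
              .groups = "drop") |>
    arrange(.data$region)
  best_val <- max(out$value)
  at_best <- out$value == best_val
  out$tied <- at_best & sum(at_best) > 1
  out$best <- FALSE
  out$best[which(at_best)[1]] <- TRUE  # alphabetical first on ties
  attr(out, "statistic") <- statistic
  out
}

#' Heatmap of a prediction surface
#'
#' Grey cells are masked (nodata or outside the training environmental
#' range). Pass `households` to overplot their locations as circles.
#'
#' @param object A `prediction_surface`.
#' @param households Optional tibble with `lon`, `lat`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prediction_surface
#' @export
autoplot.prediction_surface <- function(object, households = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$lon, .data$lat)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$predicted)) +
    ggplot2::scale_fill_viridis_c(na.value = "grey80", name = "predicted (g)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "longitude", y = "latitude")
  if (!is.null(households)) {
    p <- p + ggplot2::geom_point(data = households, shape = 1, alpha = 0.6)
  }
  p
}
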