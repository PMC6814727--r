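# Componentwise L2 gradient boosting with P-spline base-learners.
#
# Each base-learner is the penalized least-squares smooth of the current
# residual on one covariate's B-spline basis, subject to a sum-to-zero
# constraint on the fitted values (1'Bv = 0) so the constant is carried by the
# offset and never absorbed into a spline. The constraint is handled by
# reparameterizing with an orthonormal null-space basis Z of the constraint
# vector colSums(B); fitted values are invariant to the choice of Z.

# precompute everything a base-learner needs for repeated residual fits
make_learner <- function(basis, x, lambda) {
  B <- eval_basis(basis, x)
  K <- pspline_penalty(basis)
  cvec <- colSums(B)
  Z <- qr.Q(qr(matrix(cvec, ncol = 1)), complete = TRUE)[, -1, drop = FALSE]
  Bt <- B %*% Z
  Kt <- crossprod(Z, K %*% Z)
  M <- solve(crossprod(Bt) + lambda * Kt, t(Bt))  # theta = M %*% u
  list(basis = basis, lambda = lambda, Z = Z, Bt = Bt, M = M)
}

#' Fit a componentwise L2-boosted additive model of weight on environment
#'
#' Implements functional gradient descent for squared-error loss with one
#' penalized B-spline (P-spline) base-learner per environmental covariate.
#' The model starts from the offset (the mean response); at every iteration
#' each base-learner is fitted to the current residuals, the one with the
#' smallest in-bag residual sum of squares is selected (ties broken by lowest
#' column index), and the fit advances by a small step `nu` in that
#' direction. Early stopping is handled separately by [cv_mstop()]; the fit
#' stores the full path so it can be truncated at any iteration.
#'
#' All base-learners are calibrated to the same effective degrees of freedom
#' (`target_df`) so selection is comparable across covariates. Constant
#' covariates cannot support a spline and are dropped with a warning.
#'
#' @param data A data frame whose columns are the response plus the numeric
#'   environmental covariates (one column per candidate base-learner).
#' @param response Name of the response column (character scalar).
#' @param nu Step length (learning rate), default 0.1.
#' @param m_max Number of boosting iterations to run (default 100).
#' @param knots,degree,penalty_order,target_df Base-learner configuration,
#'   passed to [pspline_basis()] and [calibrate_lambda()].
#' @param learners Optional precomputed learner list (internal use by
#'   [cv_mstop()]).
#'
#' @return An object of class `boost_fit` with elements `offset`, `coef`
#'   (accumulated raw basis coefficients per covariate), `selection_history`
#'   (covariate chosen at each iteration), `inbag_risk` (mean squared
#'   training risk per iteration, index 1 = offset-only model), `steps`
#'   (per-iteration coefficient increments, enabling truncation), the basis
#'   specifications, and the training data.
#' @seealso [predict.boost_fit()], [cv_mstop()], [variable_importance()]
#' @examples
#' d <- data.frame(x1 = runif(40), x2 = runif(40))
#' d$y <- sin(2 * pi * d$x1) + rnorm(40, sd = 0.1)
#' fit <- boost_gam(d, "y", m_max = 50)
#' glance(fit)
#' @export
boost_gam <- function(data, response, nu = 0.1, m_max = 100,
                      knots = 20, degree = 3, penalty_order = 2,
                      target_df = 4, learners = NULL) {
  if (!is.data.frame(data)) abort_invalid("`data` must be a data frame")
  check_columns(data, response, "`data`")
  if (m_max < 0) abort_invalid("`m_max` must be >= 0")
  y <- data[[response]]
  X <- data[setdiff(names(data), response)]
  if (ncol(X) < 1) abort_invalid("no covariate columns in `data`")
  if (!all(vapply(X, is.numeric, logical(1)))) {
    abort_invalid("all covariates must be numeric")
  }
  if (anyNA(y) || anyNA(X) || any(!is.finite(y))) {
    abort("missing or non-finite values in the model data", class = "pdmboost_data_error")
  }
  n <- length(y)
  if (n < 2) abort_invalid("need at least 2 rows")

  if (is.null(learners)) {
    learners <- build_learners(X, knots = knots, degree = degree,
                               penalty_order = penalty_order,
                               target_df = target_df)
  }
  vars <- names(learners)
  if (length(vars) == 0) {
    abort("no usable (non-constant) covariates", class = "pdmboost_degenerate_basis")
  }

  offset <- mean(y)
  F_hat <- rep(offset, n)
  risk <- numeric(m_max + 1)
  risk[1] <- mean((y - F_hat)^2)
  selection <- character(m_max)
  steps <- vector("list", m_max)

  if (m_max > 0) {
    for (m in seq_len(m_max)) {
      u <- y - F_hat
      best_j <- 0L; best_rss <- Inf; best_theta <- NULL
      for (j in seq_along(vars)) {
        L <- learners[[j]]
        theta <- L$M %*% u
        g <- L$Bt %*% theta
        rss <- sum((u - g)^2)
        if (rss < best_rss) {
          best_rss <- rss; best_j <- j; best_theta <- theta
        }
      }
      L <- learners[[best_j]]
      F_hat <- F_hat + nu * drop(L$Bt %*% best_theta)
      selection[m] <- vars[best_j]
      steps[[m]] <- nu * drop(L$Z %*% best_theta)
      risk[m + 1] <- mean((y - F_hat)^2)
    }
  }

  coef <- lapply(setNames(vars, vars), function(v) {
    p <- learners[[v]]$basis$dim
    numeric(p)
  })
  for (m in seq_len(m_max)) {
    v <- selection[m]
    coef[[v]] <- coef[[v]] + steps[[m]]
  }

  structure(
    list(
      offset = offset,
      nu = nu,
      m_stop = m_max,
      vars = vars,
      bases = lapply(learners, function(L) L$basis),
      lambdas = vapply(learners, function(L) L$lambda, numeric(1)),
      coef = coef,
      selection_history = selection,
      inbag_risk = risk,
      steps = steps,
      response = response,
      data = data
    ),
    class = "boost_fit"
  )
}

# build one learner per non-constant covariate; constants dropped with warning
build_learners <- function(X, knots, degree, penalty_order, target_df) {
  learners <- list()
  for (v in names(X)) {
    x <- X[[v]]
    b <- tryCatch(
      pspline_basis(x, knots = knots, degree = degree,
                    penalty_order = penalty_order, var = v),
      pdmboost_degenerate_basis = function(e) {
        warn(sprintf("dropping constant covariate '%s'", v))
        NULL
      }
    )
    if (is.null(b)) next
    lambda <- calibrate_lambda(b, x, target_df = target_df)
    learners[[v]] <- make_learner(b, x, lambda)
  }
  learners
}

# accumulated raw coefficients after the first m iterations
coef_at <- function(fit, m) {
  stopifnot(inherits(fit, "boost_fit"))
  if (m == fit$m_stop) return(fit$coef)
  if (m < 0 || m > fit$m_stop) abort_invalid("`m` must be between 0 and the iterations run")
  coef <- lapply(fit$coef, function(cf) numeric(length(cf)))
  for (i in seq_len(m)) {
    v <- fit$selection_history[i]
    coef[[v]] <- coef[[v]] + fit$steps[[i]]
  }
  coef
}

#' Predict from a componentwise-boosted additive model
#'
#' Evaluates `offset + sum_j B_j(x_j) coef_j` with the coefficient path
#' truncated at iteration `m`. Covariate values outside a base-learner's
#' training range are extrapolated linearly from the boundary (see
#' [eval_basis()]); spatial applications should combine predictions with
#' [env_range_mask()] rather than trust extrapolation.
#'
#' @param object A `boost_fit`.
#' @param newdata Data frame containing every covariate column the fit uses.
#' @param m Iteration at which to truncate the path (default: all iterations
#'   run). `m = 0` gives the constant offset.
#' @param ... Unused.
#' @return Numeric vector of predictions (grams), one per row of `newdata`.
#' @export
predict.boost_fit <- function(object, newdata = object$data, m = object$m_stop, ...) {
  check_columns(newdata, object$vars, "`newdata`")
  coef <- coef_at(object, m)
  pred <- rep(object$offset, nrow(newdata))
  for (v in object$vars) {
    cf <- coef[[v]]
    if (all(cf == 0)) next
    pred <- pred + drop(eval_basis(object$bases[[v]], newdata[[v]]) %*% cf)
  }
  pred
}

#' Variable importance by accumulated in-bag risk reduction
#'
#' At every boosting iteration the drop in in-bag mean squared risk is
#' credited to the base-learner selected at that iteration; summing the
#' credits per covariate measures each variable's contribution to fitting the
#' data. The importances are non-negative and sum exactly to
#' `risk(0) - risk(m)`.
#'
#' @param fit A `boost_fit`.
#' @param m Truncation iteration (default: all iterations run).
#' @return A tibble with columns `variable`, `reduction` (grams^2), `share`
#'   (fraction of the total reduction), and `rank` (1 = most important; ties
#'   broken by covariate order and flagged via the `tied` column). The total
#'   reduction is attached as attribute `"total"`.
#' @export
variable_importance <- function(fit, m = fit$m_stop) {
  stopifnot(inherits(fit, "boost_fit"))
  if (m < 0 || m > fit$m_stop) abort_invalid("`m` out of range")
  if (m == 0) {
    out <- tibble(variable = character(), reduction = numeric(),
                  share = numeric(), rank = integer(), tied = logical())
    attr(out, "total") <- 0
    return(out)
  }
  drops <- -diff(fit$inbag_risk[seq_len(m + 1)])
  sel <- fit$selection_history[seq_len(m)]
  red <- vapply(setNames(fit$vars, fit$vars),
                function(v) sum(drops[sel == v]), numeric(1))
  total <- sum(red)
  ord <- order(-red)  # stable: ties keep covariate order
  out <- tibble(
    variable = fit$vars[ord],
    reduction = unname(red[ord]),
    share = if (total > 0) unname(red[ord]) / total else rep(0, length(red)),
    rank = seq_along(red)
  )
  out$tied <- duplicated(out$reduction) | duplicated(out$reduction, fromLast = TRUE)
  attr(out, "total") <- total
  out
}

#' @export
print.boost_fit <- function(x, ...) {
  cat(sprintf("Componentwise L2-boosted additive model (%d base-learners)\n",
              length(x$vars)))
  cat(sprintf("  offset %.2f, nu = %g, iterations = %d\n", x$offset, x$nu, x$m_stop))
  cat(sprintf("  in-bag MSE: %.4g -> %.4g\n",
              x$inbag_risk[1], x$inbag_risk[length(x$inbag_risk)]))
  sel <- unique(x$selection_history[x$selection_history != ""])
  if (length(sel)) cat("  selected:", paste(sel, collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn variable_importance `tidy()` method: the importance table.
#' @param x A `boost_fit` (for `tidy`).
#' @param ... Unused.
#' @method tidy boost_fit
#' @export
tidy.boost_fit <- function(x, m = x$m_stop, ...) {
  variable_importance(x, m = m)
}

#' One-row model summary of a boosted fit
#'
#' @param x A `boost_fit`.
#' @param ... Unused.
#' @return A one-row tibble: offset, iterations run, number of base-learners,
#'   number of distinct covariates selected, initial and final in-bag MSE.
#' @method glance boost_fit
#' @export
glance.boost_fit <- function(x, ...) {
  tibble(
    offset = x$offset,
    nu = x$nu,
    iterations = x$m_stop,
    n_learners = length(x$vars),
    n_selected = length(unique(x$selection_history[x$selection_history != ""])),
    risk_initial = x$inbag_risk[1],
    risk_final = x$inbag_risk[length(x$inbag_risk)],
    nobs = nrow(x$data)
  )
}

#' Plot the in-bag risk path or importance of a boosted fit
#'
#' @param object A `boost_fit`.
#' @param type `"risk"` for the in-bag risk path, `"importance"` for the
#'   per-variable risk-reduction bars.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot boost_fit
#' @export
autoplot.boost_fit <- function(object, type = c("risk", "importance"), ...) {
  type <- match.arg(type)
  if (type == "risk") {
    d <- tibble(iteration = seq_along(object$inbag_risk) - 1L,
                risk = object$inbag_risk)
    ggplot2::ggplot(d, ggplot2::aes(.data$iteration, .data$risk)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "boosting iteration", y = "in-bag MSE (g²)")
  } else {
    d <- variable_importance(object)
    ggplot2::ggplot(d, ggplot2::aes(stats::reorder(.data$variable, .data$reduction),
                                    .data$reduction)) +
      ggplot2::geom_col() +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "accumulated in-bag risk reduction (g²)")
  }
}
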