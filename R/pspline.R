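#' Construct a P-spline basis specification for one covariate
#'
#' Sets up a cubic (by default) B-spline basis with equally spaced interior
#' knots over the covariate's training range and a difference penalty on
#' adjacent coefficients. This is the standard P-spline construction used for
#' the weak base-learners of the componentwise boosting model: every covariate
#' gets the same basis layout so that, once the penalty is calibrated to a
#' common effective degrees of freedom, base-learner selection is not biased
#' toward more flexible variables.
#'
#' The basis spans `knots` equal-width segments over `range`, extended by
#' `degree` extra knots on each side, giving `knots + degree` basis functions.
#' Evaluation outside the training range extrapolates linearly from the
#' boundary (value plus first derivative at the boundary), so spatial
#' prediction degrades gracefully just outside the support; cells genuinely
#' outside the support are the business of [env_range_mask()].
#'
#' @param x Numeric vector of training covariate values (defines the range).
#' @param knots Number of interior knot segments (default 20).
#' @param degree Spline degree (default 3, cubic).
#' @param penalty_order Order of the difference penalty (default 2).
#' @param range Optional length-2 numeric giving the training range; defaults
#'   to `range(x)`.
#' @param var Optional variable name carried for bookkeeping.
#'
#' @return An object of class `pspline_basis`: a list with the full knot
#'   vector, degree, penalty order, training range and basis dimension.
#' @seealso [eval_basis()], [calibrate_lambda()], [boost_gam()]
#' @export
pspline_basis <- function(x, knots = 20, degree = 3, penalty_order = 2,
                          range = NULL, var = NULL) {
  if (!is.numeric(x) || length(x) < 2) {
    abort_invalid("`x` must be a numeric vector with at least 2 values")
  }
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2) {
    abort(
      sprintf("covariate%s is constant: cannot build a spline basis",
              if (is.null(var)) "" else paste0(" '", var, "'")),
      class = "pdmboost_degenerate_basis"
    )
  }
  stopifnot(knots >= 1, degree >= 1, penalty_order >= 1)
  rng <- range %||% base::range(x)
  if (!(rng[1] < rng[2])) abort_invalid("training range must satisfy min < max")
  h <- (rng[2] - rng[1]) / knots
  inner <- seq(rng[1], rng[2], length.out = knots + 1)  # endpoints exact
  knot_seq <- c(rng[1] - h * (degree:1), inner, rng[2] + h * (1:degree))
  structure(
    list(
      var = var,
      knots = knot_seq,
      degree = degree,
      penalty_order = penalty_order,
      range = rng,
      dim = knots + degree
    ),
    class = "pspline_basis"
  )
}

#' Evaluate a P-spline basis at new covariate values
#'
#' Returns the design matrix of the basis at `x`. Inside the training range
#' this is the usual B-spline design; outside, rows are linear extrapolations
#' from the nearest boundary: `B(x) = B(b) + B'(b) (x - b)`.
#'
#' @param basis A [pspline_basis()] object.
#' @param x Numeric vector of evaluation points.
#' @return A numeric matrix with `length(x)` rows and `basis$dim` columns.
#' @export
eval_basis <- function(basis, x) {
  stopifnot(inherits(basis, "pspline_basis"))
  if (!is.numeric(x)) abort_invalid("`x` must be numeric")
  ord <- basis$degree + 1L
  a <- basis$range[1]; b <- basis$range[2]
  out <- matrix(0, nrow = length(x), ncol = basis$dim)
  if (length(x) == 0) return(out)
  inside <- x >= a & x <= b
  if (any(inside)) {
    out[inside, ] <- splines::splineDesign(basis$knots, x[inside], ord = ord)
  }
  for (side in c("lo", "hi")) {
    sel <- if (side == "lo") x < a else x > b
    if (!any(sel)) next
    bd <- if (side == "lo") a else b
    v <- splines::splineDesign(basis$knots, bd, ord = ord)
    d <- splines::splineDesign(basis$knots, bd, ord = ord, derivs = 1L)
    out[sel, ] <- rep(1, sum(sel)) %o% drop(v) + (x[sel] - bd) %o% drop(d)
  }
  out
}

# difference-penalty matrix K = D'D for a basis of dimension p
pspline_penalty <- function(basis) {
  D <- diff(diag(basis$dim), differences = basis$penalty_order)
  crossprod(D)
}

# trace of the penalized smoother hat matrix: df(lambda) = tr(B (B'B + l K)^-1 B')
pspline_df <- function(B, K, lambda) {
  M <- crossprod(B) + lambda * K
  sum(diag(solve(M, crossprod(B))))
}

#' Calibrate the P-spline penalty to a target effective degrees of freedom
#'
#' Finds the penalty weight `lambda` such that the effective degrees of
#' freedom of the penalized smoother, `trace(B (B'B + lambda D'D)^-1 B')`,
#' equals `target_df` (default 4). Calibration uses monotone bisection on
#' `log(lambda)`; `df(lambda)` decreases from the basis rank at `lambda = 0`
#' to the penalty null-space dimension (`penalty_order`) as `lambda` grows,
#' so any target strictly between those limits is reachable.
#'
#' Giving every base-learner the same small `target_df` is what makes
#' componentwise selection comparable across covariates.
#'
#' @param basis A [pspline_basis()] object.
#' @param x Training covariate values.
#' @param target_df Target effective degrees of freedom (default 4).
#' @param tol Absolute tolerance on the achieved df (default 1e-6).
#' @return The calibrated `lambda` (a positive scalar).
#' @export
calibrate_lambda <- function(basis, x, target_df = 4, tol = 1e-6) {
  stopifnot(inherits(basis, "pspline_basis"))
  if (target_df >= basis$dim) {
    abort_invalid("`target_df` must be smaller than the basis dimension",
                  class = "pdmboost_calibration_error")
  }
  B <- eval_basis(basis, x)
  K <- pspline_penalty(basis)
  # reachable window: df -> rank(B) as lambda -> 0, df -> penalty_order as
  # lambda -> Inf
  df_at <- function(ll) pspline_df(B, K, exp(ll))
  lo <- log(1e-10); hi <- log(1e10)
  # expand until the target is bracketed (df decreasing in lambda)
  for (i in 1:60) {
    if (df_at(lo) >= target_df) break
    lo <- lo - 5
  }
  for (i in 1:60) {
    if (df_at(hi) <= target_df) break
    hi <- hi + 5
  }
  if (df_at(lo) < target_df - tol || df_at(hi) > target_df + tol) {
    abort(
      sprintf("target_df = %g is unreachable for this basis (achievable df in [%.4f, %.4f])",
              target_df, df_at(hi), df_at(lo)),
      class = "pdmboost_calibration_error"
    )
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    d <- df_at(mid)
    if (abs(d - target_df) < tol) return(exp(mid))
    if (d > target_df) lo <- mid else hi <- mid
  }
  exp((lo + hi) / 2)
}

#' @export
print.pspline_basis <- function(x, ...) {
  cat(sprintf(
    "P-spline basis%s: degree %d, %d basis functions, penalty order %d, range [%g, %g]\n",
    if (is.null(x$var)) "" else paste0(" for '", x$var, "'"),
    x$degree, x$dim, x$penalty_order, x$range[1], x$range[2]
  ))
  invisible(x)
}
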