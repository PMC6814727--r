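# Resampled empirical risk for early stopping.

# one boosting run on an in-bag set, tracking out-of-bag MSE per iteration
boost_path_oob <- function(learners, y_in, P_oob, y_oob, nu, m_max) {
  n_in <- length(y_in)
  F_in <- rep(mean(y_in), n_in)
  F_oob <- rep(mean(y_in), length(y_oob))
  risk_oob <- numeric(m_max + 1)
  risk_oob[1] <- mean((y_oob - F_oob)^2)
  for (m in seq_len(m_max)) {
    u <- y_in - F_in
    best_j <- 0L; best_rss <- Inf; best_theta <- NULL
    for (j in seq_along(learners)) {
      L <- learners[[j]]
      theta <- L$M %*% u
      g <- L$Bt %*% theta
      rss <- sum((u - g)^2)
      if (rss < best_rss) { best_rss <- rss; best_j <- j; best_theta <- theta }
    }
    L <- learners[[best_j]]
    F_in <- F_in + nu * drop(L$Bt %*% best_theta)
    F_oob <- F_oob + nu * drop(P_oob[[best_j]] %*% best_theta)
    risk_oob[m + 1] <- mean((y_oob - F_oob)^2)
  }
  risk_oob
}

#' Choose the boosting stopping iteration by resampled out-of-bag risk
#'
#' Draws `B` resamples of the training rows (bootstrap with replacement by
#' default, or k-fold cross-validation), reruns the componentwise boosting
#' path on each in-bag set with the same base-learner bases and penalties as
#' the full-data fit, records the out-of-bag mean squared error at every
#' iteration, and returns the iteration minimizing the across-resample mean
#' risk. On ties the smallest iteration wins. A separate stopping iteration
#' is determined this way for every model (breed by sex by phase).
#'
#' @param fit A [boost_gam()] fit (its data, bases, penalties, `nu` and
#'   `m_max` define the path to be resampled).
#' @param B Number of resamples (default 25).
#' @param scheme `"bootstrap"` (default) or `"kfold"`.
#' @param folds Number of folds when `scheme = "kfold"` (default 10).
#' @param seed Integer seed for the resampling; the caller's RNG state is
#'   left untouched.
#' @param m_max Maximum iteration to evaluate (default: the fit's).
#'
#' @return An object of class `cv_risk`: list with the `risk` matrix
#'   (resample by iteration, columns 0..m_max), `m_stop`, `scheme`, `seed`.
#' @export
cv_mstop <- function(fit, B = 25, scheme = c("bootstrap", "kfold"),
                     folds = 10, seed = NULL, m_max = fit$m_stop) {
  stopifnot(inherits(fit, "boost_fit"))
  scheme <- match.arg(scheme)
  if (B < 2) abort_invalid("`B` must be >= 2")
  if (m_max < 1) abort_invalid("`m_max` must be >= 1")
  y <- fit$data[[fit$response]]
  X <- fit$data[fit$vars]
  n <- length(y)

  index_sets <- with_seed(seed, {
    if (scheme == "bootstrap") {
      lapply(seq_len(B), function(b) {
        for (try in 1:100) {
          idx <- sample.int(n, n, replace = TRUE)
          if (length(unique(idx)) >= 2 && length(setdiff(seq_len(n), idx)) >= 1) {
            return(idx)
          }
        }
        abort("could not draw a usable bootstrap resample", class = "pdmboost_resample_error")
      })
    } else {
      fold_id <- sample(rep_len(seq_len(folds), n))
      lapply(seq_len(folds), function(k) which(fold_id != k))
    }
  })
  if (scheme == "kfold") B <- length(index_sets)

  risk <- matrix(NA_real_, nrow = B, ncol = m_max + 1)
  for (b in seq_len(B)) {
    idx <- index_sets[[b]]
    oob <- setdiff(seq_len(n), idx)
    if (length(oob) == 0) next
    learners <- lapply(fit$vars, function(v) {
      make_learner(fit$bases[[v]], X[[v]][idx], fit$lambdas[[v]])
    })
    P_oob <- lapply(seq_along(fit$vars), function(j) {
      eval_basis(fit$bases[[fit$vars[j]]], X[[fit$vars[j]]][oob]) %*% learners[[j]]$Z
    })
    risk[b, ] <- boost_path_oob(learners, y[idx], P_oob, y[oob], fit$nu, m_max)
  }
  ok <- !apply(risk, 1, function(r) all(is.na(r)))
  mean_risk <- colMeans(risk[ok, , drop = FALSE])
  m_stop <- which.min(mean_risk) - 1L  # first minimum = smallest m on ties

  structure(
    list(risk = risk[ok, , drop = FALSE], mean_risk = mean_risk,
         m_stop = m_stop, scheme = scheme, B = sum(ok), seed = seed,
         nu = fit$nu),
    class = "cv_risk"
  )
}

#' @export
print.cv_risk <- function(x, ...) {
  cat(sprintf("Resampled empirical risk (%s, B = %d): m_stop = %d\n",
              x$scheme, x$B, x$m_stop))
  invisible(x)
}

#' @describeIn cv_mstop `tidy()` method: long tibble of (resample,
#'   iteration, oob_risk).
#' @param x A `cv_risk` (for `tidy`).
#' @param ... Unused.
#' @method tidy cv_risk
#' @export
tidy.cv_risk <- function(x, ...) {
  as_tibble(x$risk, .name_repair = ~ as.character(seq_along(.x) - 1L)) |>
    mutate(resample = dplyr::row_number()) |>
    pivot_longer(-"resample", names_to = "iteration", values_to = "oob_risk") |>
    mutate(iteration = as.integer(.data$iteration))
}

#' @method autoplot cv_risk
#' @export
autoplot.cv_risk <- function(object, ...) {
  d <- tidy(object)
  m <- tibble(iteration = seq_along(object$mean_risk) - 1L,
              oob_risk = object$mean_risk)
  ggplot2::ggplot(d, ggplot2::aes(.data$iteration, .data$oob_risk,
                                  group = .data$resample)) +
    ggplot2::geom_line(alpha = 0.25) +
    ggplot2::geom_line(data = m, ggplot2::aes(group = NULL), linewidth = 1) +
    ggplot2::geom_vline(xintercept = object$m_stop, linetype = 2) +
    ggplot2::labs(x = "boosting iteration", y = "out-of-bag MSE (g²)")
}
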