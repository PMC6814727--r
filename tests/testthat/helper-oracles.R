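# Independent reference implementations used as oracles. They deliberately
# share no code path with the package internals: basis matrices come straight
# from splines::splineDesign on the stored knot vectors, the sum-to-zero
# constraint is imposed through a KKT (Lagrange multiplier) augmented system
# rather than a null-space reparameterization, and the boosting loop is a
# naive double loop with a fresh dense solve at every step.

# constrained penalized least-squares fit of u on one basis:
# min ||u - B v||^2 + lambda v'Kv  s.t.  colSums(B) v = 0
naive_base_fit <- function(B, K, lambda, u) {
  p <- ncol(B)
  cvec <- colSums(B)
  A <- rbind(cbind(crossprod(B) + lambda * K, cvec),
             c(cvec, 0))
  rhs <- c(crossprod(B, u), 0)
  sol <- solve(A, rhs)
  v <- sol[seq_len(p)]
  list(coef = v, fitted = drop(B %*% v))
}

naive_penalty <- function(p, order) {
  D <- diff(diag(p), differences = order)
  crossprod(D)
}

# naive componentwise L2 boosting; bases is a list of pspline_basis objects
# (their knot vectors are data, not code), lambdas a named numeric vector
naive_boost <- function(X, y, nu, m_max, bases, lambdas) {
  vars <- names(bases)
  Bs <- lapply(vars, function(v) {
    b <- bases[[v]]
    splines::splineDesign(b$knots, X[[v]], ord = b$degree + 1)
  })
  names(Bs) <- vars
  Ks <- lapply(vars, function(v) {
    b <- bases[[v]]
    naive_penalty(ncol(Bs[[v]]), b$penalty_order)
  })
  names(Ks) <- vars
  F_hat <- rep(mean(y), length(y))
  risk <- mean((y - F_hat)^2)
  selection <- character(0)
  for (m in seq_len(m_max)) {
    u <- y - F_hat
    rss <- rep(NA_real_, length(vars))
    fits <- vector("list", length(vars))
    for (j in seq_along(vars)) {
      v <- vars[j]
      fits[[j]] <- naive_base_fit(Bs[[v]], Ks[[v]], lambdas[[v]], u)
      rss[j] <- sum((u - fits[[j]]$fitted)^2)
    }
    j_star <- which.min(rss)  # first minimum = lowest index
    F_hat <- F_hat + nu * fits[[j_star]]$fitted
    selection <- c(selection, vars[j_star])
    risk <- c(risk, mean((y - F_hat)^2))
  }
  list(selection = selection, risk = risk, fitted = F_hat)
}

# random small boosting instance generator (covariates strictly inside a
# [0, 1] range so the oracle never needs boundary extrapolation)
random_boost_instance <- function(seed, n_max = 15, n_vars = 3) {
  withr::with_seed(seed, {
    n <- sample(5:n_max, 1)
    X <- as.data.frame(matrix(runif(n * n_vars), nrow = n))
    names(X) <- paste0("x", seq_len(n_vars))
    y <- rnorm(n, sd = 1) + 2 * X[[1]]^2
    list(X = X, y = y)
  })
}

# tiny contaminated simulation shared by cleaning/evaluation tests
small_sim <- function(seed = 11, n_households = 30,
                      contamination = list(under50 = 4, over30 = 2, under6wk = 3)) {
  stack <- sim_env_stack(12, 12, n_vars = 5, n_regions = 3, smoothness = 2,
                         seed = seed)
  hh <- sim_households(stack, n_households, c("breed_a", "breed_b"),
                       seed = seed + 1)
  spec <- surface_spec(
    active_vars = "var01",
    component_functions = list(var01 = function(x) 2 * x),
    household_sd = 30, residual_sd = 20, slope_sd = 4
  )
  sim <- sim_weight_records(hh, stack, spec = spec,
                            contamination = contamination, seed = seed + 2)
  list(stack = stack, households = hh, sim = sim, spec = spec)
}
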