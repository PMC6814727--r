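# The componentwise boosting core: basis construction, penalty calibration,
# the boosting path, early stopping and importance.

test_that("B-spline basis has the textbook layout and partition of unity", {
  x <- seq(0, 1, length.out = 60)
  for (cfg in list(c(20, 3), c(10, 2), c(5, 1))) {
    b <- pspline_basis(x, knots = cfg[1], degree = cfg[2])
    B <- eval_basis(b, x)
    expect_equal(ncol(B), cfg[1] + cfg[2])  # dim = segments + degree
    expect_equal(rowSums(B), rep(1, length(x)), tolerance = 1e-12)
  }
  # boundary points evaluate without error and keep partition of unity
  b <- pspline_basis(c(0.3, 1.7, 0.9), knots = 7)
  B <- eval_basis(b, c(0.3, 1.7))
  expect_equal(rowSums(B), c(1, 1), tolerance = 1e-12)
  expect_error(pspline_basis(rep(2, 10)), class = "pdmboost_degenerate_basis")
})

test_that("basis evaluation extrapolates linearly outside the training range", {
  x <- seq(0, 1, length.out = 40)
  b <- pspline_basis(x)
  cf <- rnorm(b$dim)
  f <- function(z) drop(eval_basis(b, z) %*% cf)
  # second differences vanish on each side => linear in x
  lo <- f(c(-0.3, -0.2, -0.1))
  hi <- f(c(1.1, 1.25, 1.4))
  expect_equal(diff(lo, differences = 2), 0, tolerance = 1e-10,
               ignore_attr = TRUE)
  # continuity and slope matching at the boundary
  eps <- 1e-6
  expect_equal(f(1 + eps) - f(1), f(1) - f(1 - eps), tolerance = 1e-4)
})

test_that("penalty calibration hits the target df and the known limits", {
  withr::with_seed(5, {
    x <- runif(200)
  })
  b <- pspline_basis(x, knots = 5, degree = 3, penalty_order = 2)
  B <- eval_basis(b, x)
  K <- diff(diag(b$dim), differences = 2) |> crossprod()
  # lambda -> 0: df -> basis rank; lambda -> Inf: df -> penalty null space
  df_at <- function(l) sum(diag(B %*% solve(crossprod(B) + l * K) %*% t(B)))
  expect_equal(df_at(1e-12), qr(B)$rank, tolerance = 1e-6)
  expect_equal(df_at(1e12), 2, tolerance = 1e-6)
  # calibration on a fixed 50-point sample, rechecked with an explicit dense
  # hat-matrix trace
  withr::with_seed(6, x50 <- runif(50))
  b50 <- pspline_basis(x50)
  lam <- calibrate_lambda(b50, x50, target_df = 4)
  B50 <- eval_basis(b50, x50)
  K50 <- diff(diag(b50$dim), differences = 2) |> crossprod()
  H <- B50 %*% solve(crossprod(B50) + lam * K50) %*% t(B50)
  expect_equal(sum(diag(H)), 4, tolerance = 1e-6)
  expect_error(calibrate_lambda(b50, x50, target_df = b50$dim + 1),
               class = "pdmboost_calibration_error")
})

test_that("offset-only and single-step fits match closed forms", {
  withr::with_seed(7, {
    x <- runif(30)
    y <- 300 + 100 * x + rnorm(30, sd = 10)
  })
  d <- data.frame(y = y, x = x)
  # m_max = 0: constant offset, risk path = population MSE of the mean
  fit0 <- boost_gam(d, "y", m_max = 0)
  expect_equal(predict(fit0, d), rep(mean(y), 30))
  expect_equal(fit0$inbag_risk, mean((y - mean(y))^2))
  # one variable, nu = 1, m = 1: exactly the single constrained penalized
  # least-squares smooth of y around its mean (independent KKT oracle)
  fit1 <- boost_gam(d, "y", nu = 1, m_max = 1)
  b <- fit1$bases$x
  B <- splines::splineDesign(b$knots, x, ord = b$degree + 1)
  K <- naive_penalty(ncol(B), b$penalty_order)
  oracle <- naive_base_fit(B, K, fit1$lambdas[["x"]], y - mean(y))
  expect_equal(predict(fit1, d), mean(y) + oracle$fitted, tolerance = 1e-10)
})

test_that("selection, risk path and importance match the brute-force oracle", {
  for (seed in c(101, 202, 303)) {
    inst <- random_boost_instance(seed)
    d <- cbind(data.frame(y = inst$y), inst$X)
    fit <- boost_gam(d, "y", nu = 0.1, m_max = 10)
    ref <- naive_boost(inst$X, inst$y, nu = 0.1, m_max = 10,
                       bases = fit$bases, lambdas = fit$lambdas)
    expect_identical(fit$selection_history, ref$selection)
    expect_equal(fit$inbag_risk, ref$risk, tolerance = 1e-10)
    expect_equal(predict(fit, d), ref$fitted, tolerance = 1e-10)
  }
})

test_that("noise-free single-signal data selects only the active variable", {
  withr::with_seed(9, {
    X <- data.frame(x1 = runif(40), x2 = runif(40), x3 = runif(40))
  })
  d <- cbind(data.frame(y = sin(2 * pi * X$x1)), X)
  fit <- boost_gam(d, "y", m_max = 40)
  expect_setequal(unique(fit$selection_history), "x1")
  imp <- variable_importance(fit)
  expect_equal(imp$variable[1], "x1")
  expect_equal(imp$reduction[imp$variable != "x1"], c(0, 0))
})

test_that("risk paths are non-increasing and importance is conserved", {
  fits <- list(
    boost_gam(cbind(data.frame(y = random_boost_instance(1)$y),
                    random_boost_instance(1)$X), "y", m_max = 25),
    boost_gam(cbind(data.frame(y = random_boost_instance(2, n_max = 12)$y),
                    random_boost_instance(2, n_max = 12)$X), "y",
              nu = 0.3, m_max = 60)
  )
  for (fit in fits) {
    expect_true(all(diff(fit$inbag_risk) <= 1e-12 * fit$inbag_risk[1]))
    for (m in c(0, 5, fit$m_stop)) {
      imp <- variable_importance(fit, m = m)
      expect_equal(attr(imp, "total"),
                   fit$inbag_risk[1] - fit$inbag_risk[m + 1],
                   tolerance = 1e-12)
      expect_true(all(imp$reduction >= 0))
    }
  }
})

test_that("fits are equivariant to row and column permutations", {
  inst <- random_boost_instance(77, n_max = 14)
  d <- cbind(data.frame(y = inst$y), inst$X)
  fit <- boost_gam(d, "y", m_max = 15)
  grid <- data.frame(x1 = seq(0.1, 0.9, 0.1), x2 = 0.5, x3 = 0.5)
  perm <- withr::with_seed(8, sample(nrow(d)))
  fit_rows <- boost_gam(d[perm, ], "y", m_max = 15)
  expect_equal(predict(fit_rows, grid), predict(fit, grid), tolerance = 1e-10)
  fit_cols <- boost_gam(d[, c("y", "x3", "x1", "x2")], "y", m_max = 15)
  expect_identical(fit_cols$selection_history, fit$selection_history)
  expect_equal(predict(fit_cols, grid), predict(fit, grid), tolerance = 1e-10)
})

test_that("long boosting of one base-learner converges to the unpenalized fit", {
  # twicing: repeated shrunken smoothing approaches the projection on the
  # basis span; checked on a small basis where 5000 steps reach the limit
  withr::with_seed(10, {
    x <- seq(0, 1, length.out = 30)
    y <- sin(2 * pi * x) + 0.3 * cos(5 * x) + rnorm(30, sd = 0.2)
  })
  d <- data.frame(y = y, x = x)
  fit <- boost_gam(d, "y", nu = 0.1, m_max = 5000, knots = 4)
  B <- eval_basis(fit$bases$x, x)
  unpen <- qr.fitted(qr(B), y)
  expect_lt(sqrt(mean((predict(fit, d) - unpen)^2)), 1e-4)
})

test_that("cv_mstop is deterministic, bounded, and respects tie rules", {
  inst <- random_boost_instance(55, n_max = 15)
  d <- cbind(data.frame(y = inst$y), inst$X)
  fit <- boost_gam(d, "y", m_max = 20)
  cv1 <- cv_mstop(fit, B = 8, seed = 99)
  cv2 <- cv_mstop(fit, B = 8, seed = 99)
  expect_identical(cv1$risk, cv2$risk)
  expect_lte(cv1$m_stop, 20)
  expect_gte(cv1$m_stop, 0)
  expect_equal(cv1$m_stop, which.min(colMeans(cv1$risk)) - 1L)
  cvk <- cv_mstop(fit, scheme = "kfold", folds = 5, seed = 1)
  expect_equal(nrow(cvk$risk), 5)
})

test_that("boosted models survive a JSON round trip", {
  inst <- random_boost_instance(31)
  d <- cbind(data.frame(y = inst$y), inst$X)
  fit <- boost_gam(d, "y", m_max = 12)
  path <- withr::local_tempfile(fileext = ".json")
  write_boost_fit(fit, path, m = 8)
  back <- read_boost_fit(path)
  expect_equal(predict(back, d, m = 8), predict(fit, d, m = 8),
               tolerance = 1e-12)
  expect_identical(back$selection_history, fit$selection_history[1:8])
  imp_a <- variable_importance(fit, m = 8)
  imp_b <- variable_importance(back, m = 8)
  expect_equal(imp_a$reduction, imp_b$reduction, tolerance = 1e-12)
})

test_that("invalid model data is rejected with classed errors", {
  d <- data.frame(y = c(1, 2, NA), x = c(1, 2, 3))
  expect_error(boost_gam(d, "y"), class = "pdmboost_data_error")
  expect_error(boost_gam(data.frame(y = 1:5, x = 1:5), "y", m_max = -1),
               class = "pdmboost_invalid_argument")
  expect_warning(
    fit <- boost_gam(data.frame(y = rnorm(10), x = rnorm(10), z = rep(1, 10)),
                     "y", m_max = 3),
    "constant"
  )
  expect_identical(fit$vars, "x")
})
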