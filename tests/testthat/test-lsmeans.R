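# Household growth model and least-squares means.

toy_two_households <- function() {
  # noise-free lines y = 100 + 50 w and y = 100 + 30 w
  d <- tibble::tibble(
    household_id = rep(c("a", "b"), each = 3),
    week = rep(c(14, 16, 19), 2)
  )
  d$avg_weight_g <- ifelse(d$household_id == "a",
                           100 + 50 * d$week, 100 + 30 * d$week)
  d
}

test_that("noise-free two-household toy is recovered in closed form", {
  fit <- fit_household_growth(toy_two_households())
  expect_equal(fit$common_intercept, 100, tolerance = 1e-10)
  expect_equal(sort(fit$households$slope), c(30, 50), tolerance = 1e-10)
  expect_equal(fit$residual_variance, 0, tolerance = 1e-10)
  ls <- lsmeans_at_week(fit, 16)
  expect_equal(sort(ls$lsmean), c(580, 900), tolerance = 1e-10)
  expect_equal(ls$se, c(0, 0), tolerance = 1e-6)
  # eval_week = 0: every lsmean is the common intercept
  ls0 <- lsmeans_at_week(fit, 0)
  expect_equal(ls0$lsmean, c(100, 100), tolerance = 1e-10)
})

test_that("single-household fit interpolates two points exactly", {
  d <- tibble::tibble(household_id = "h", week = c(14, 18),
                      avg_weight_g = c(800, 1000))
  fit <- fit_household_growth(d)
  expect_equal(fit$households$slope, 50, tolerance = 1e-10)
  expect_equal(fit$common_intercept, 100, tolerance = 1e-10)
})

test_that("fit matches the lm() normal-equations oracle incl. standard errors", {
  withr::with_seed(21, {
    d <- tibble::tibble(
      household_id = rep(sprintf("h%02d", 1:5), times = c(4, 3, 2, 5, 1)),
      week = c(14, 15, 17, 19, 14, 16, 18, 15, 19, 14, 15, 16, 17, 18, 16)
    )
    d$avg_weight_g <- 120 + rep(c(52, 40, 61, 45, 35), times = c(4, 3, 2, 5, 1)) *
      d$week + rnorm(nrow(d), sd = 25)
  })
  fit <- fit_household_growth(d)
  lmfit <- stats::lm(avg_weight_g ~ week:household_id, data = d)
  expect_equal(fit$common_intercept, unname(coef(lmfit)[1]), tolerance = 1e-10)
  nd <- tibble::tibble(week = 16.4, household_id = sprintf("h%02d", 1:5))
  pr <- stats::predict(lmfit, nd, se.fit = TRUE)
  ls <- lsmeans_at_week(fit, 16.4)
  expect_equal(ls$lsmean, unname(pr$fit), tolerance = 1e-10)
  expect_equal(ls$se, unname(pr$se.fit), tolerance = 1e-10)
})

test_that("lsmeans agree with emmeans on the same model", {
  skip_if_not_installed("emmeans")
  withr::with_seed(22, {
    d <- tibble::tibble(
      household_id = factor(rep(c("u", "v", "w"), each = 4)),
      week = rep(c(14, 16, 18, 19), 3)
    )
    d$avg_weight_g <- 90 + rep(c(55, 48, 60), each = 4) * d$week +
      rnorm(12, sd = 15)
  })
  lmfit <- stats::lm(avg_weight_g ~ week:household_id, data = d)
  em <- as.data.frame(
    emmeans::emmeans(lmfit, ~household_id, at = list(week = 16.75))
  )
  ls <- lsmeans_at_week(fit_household_growth(d), 16.75)
  expect_equal(ls$lsmean, em$emmean, tolerance = 1e-8)
  expect_equal(ls$se, em$SE, tolerance = 1e-8)
})

test_that("duplicated observations act as case weights", {
  d <- toy_two_households()
  d$avg_weight_g <- d$avg_weight_g + withr::with_seed(3, rnorm(6, sd = 10))
  dup <- dplyr::bind_rows(d, d[2, ])
  fit_dup <- fit_household_growth(dup)
  # weighted normal equations oracle with weight 2 on the duplicated row
  w <- c(1, 2, 1, 1, 1, 1)
  Xm <- cbind(1, ifelse(d$household_id == "a", d$week, 0),
              ifelse(d$household_id == "b", d$week, 0))
  beta <- solve(t(Xm) %*% (w * Xm), t(Xm) %*% (w * d$avg_weight_g))
  expect_equal(fit_dup$common_intercept, beta[1], tolerance = 1e-10)
  expect_equal(sort(fit_dup$households$slope), sort(beta[2:3]), tolerance = 1e-10)
})

test_that("lsmeans are invariant to record order", {
  d <- toy_two_households()
  perm <- c(5, 2, 6, 1, 4, 3)
  ls1 <- lsmeans_at_week(fit_household_growth(d), 16)
  ls2 <- lsmeans_at_week(fit_household_growth(d[perm, ]), 16)
  expect_equal(ls1 |> dplyr::arrange(household_id),
               ls2 |> dplyr::arrange(household_id))
})

test_that("confounded designs and bad eval weeks raise classed errors", {
  d <- tibble::tibble(household_id = c("a", "a", "b"), week = 10,
                      avg_weight_g = c(500, 520, 480))
  expect_error(fit_household_growth(d), class = "pdmboost_rank_deficiency")
  fit <- fit_household_growth(toy_two_households())
  expect_error(lsmeans_at_week(fit, Inf), class = "pdmboost_invalid_argument")
})

test_that("noise-free synthetic data is recovered exactly at any eval week", {
  world <- small_sim(seed = 41, contamination = list())
  spec0 <- surface_spec(
    active_vars = "var01",
    component_functions = list(var01 = function(x) 2 * x),
    household_sd = 40, residual_sd = 0, slope_sd = 5
  )
  sim <- sim_weight_records(world$households, world$stack, spec = spec0,
                            seed = 43)
  avg <- to_average_weight(sim$records)
  for (ph in c("male_growing", "female_adult")) {
    recs <- split_phase(avg, ph)
    ew <- phase_average_week(recs)
    ls <- recs |>
      dplyr::group_by(breed) |>
      dplyr::group_split() |>
      purrr::map(\(d) lsmeans_at_week(fit_household_growth(d), ew)) |>
      purrr::list_rbind()
    truth <- true_weight(sim, ew)
    j <- dplyr::inner_join(ls, truth, by = "household_id")
    expect_equal(j$lsmean, j$true_weight, tolerance = 1e-8)
  }
})
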