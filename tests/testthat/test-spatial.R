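# Range masking, surface prediction and region suitability.

spatial_world <- function(seed = 61) {
  st <- sim_env_stack(15, 15, n_vars = 5, n_regions = 4, smoothness = 2,
                      seed = seed)
  hh <- sim_households(st, 60, "breed_a", seed = seed + 1)
  covs <- extract_covariates(st, hh)
  spec <- surface_spec(
    active_vars = "var01",
    component_functions = list(var01 = function(x) 4 * x),
    household_sd = 0, residual_sd = 0, slope_sd = 0
  )
  sim <- sim_weight_records(hh, st, spec = spec, seed = seed + 2)
  y <- true_weight(sim, 16.5)$true_weight
  d <- dplyr::bind_cols(tibble::tibble(y = y), covs[-1])
  fit <- boost_gam(d, "y", m_max = 200)
  list(stack = st, households = hh, covs = covs, fit = fit, sim = sim)
}

test_that("range mask is closed on the boundary and catches the desert", {
  w <- spatial_world()
  mask <- env_range_mask(w$stack, w$covs[-1])
  # training cells are never masked (closed interval at the training range)
  for (i in seq_len(nrow(w$households))) {
    expect_equal(mask[w$households$row[i], w$households$col[i]], "ok")
  }
  # a synthetic cell exactly at the training max of every variable is ok
  ranges <- attr(mask, "ranges")
  at_max <- as.data.frame(as.list(ranges[, "max"]))
  st2 <- w$stack
  st2$values[1, 1, ] <- ranges[, "max"]
  st2$nodata[1, 1] <- FALSE
  mask2 <- env_range_mask(st2, w$covs[-1])
  expect_equal(mask2[1, 1], "ok")
  # the desert's shifted layer puts 100% of its cells out of range
  desert <- w$stack$region == "desert"
  expect_true(all(mask[desert & !w$stack$nodata] == "out_of_range"))
  expect_true(all(mask[w$stack$nodata] == "nodata"))
  expect_error(env_range_mask(w$stack, w$covs[-1], vars = "missing_layer"),
               class = "pdmboost_schema_error")
})

test_that("mask is monotone under training-range enlargement", {
  w <- spatial_world(seed = 67)
  base <- env_range_mask(w$stack, w$covs[-1])
  widened <- dplyr::bind_rows(
    w$covs[-1],
    as.data.frame(as.list(sapply(w$covs[-1], min) - 1)),
    as.data.frame(as.list(sapply(w$covs[-1], max) + 1))
  )
  bigger <- env_range_mask(w$stack, widened)
  expect_true(all(bigger[base == "ok"] == "ok"))
})

test_that("surfaces predict only unmasked cells, consistently with the fit", {
  w <- spatial_world(seed = 71)
  surf <- predict_surface(w$fit, w$stack)
  expect_true(all(is.na(surf$predicted[surf$mask_reason != "ok"])))
  expect_true(all(!is.na(surf$predicted[surf$mask_reason == "ok"])))
  # surface at a household's cell equals the rowwise model prediction
  hh1 <- w$households[3, ]
  cell <- surf[surf$row == hh1$row & surf$col == hh1$col, ]
  expect_equal(cell$predicted,
               predict(w$fit, w$covs[w$covs$household_id == hh1$household_id, -1]))
  # offset-only model gives a constant surface
  fit0 <- boost_gam(dplyr::bind_cols(tibble::tibble(y = rnorm(60)), w$covs[-1]),
                    "y", m_max = 0)
  surf0 <- predict_surface(fit0, w$stack)
  expect_equal(stats::sd(surf0$predicted[surf0$mask_reason == "ok"]), 0)
  # same serialized model + same stack -> bit-identical surface
  path <- withr::local_tempfile(fileext = ".json")
  write_boost_fit(w$fit, path)
  mask <- env_range_mask(w$stack, w$covs[-1])
  surf_a <- predict_surface(read_boost_fit(path), w$stack, mask = mask)
  surf_b <- predict_surface(read_boost_fit(path), w$stack, mask = mask)
  expect_identical(surf_a$predicted, surf_b$predicted)
  expect_equal(surf_a$predicted, surf$predicted, tolerance = 1e-9)
})

test_that("region suitability ranks regions and respects masking", {
  w <- spatial_world(seed = 73)
  surf <- predict_surface(w$fit, w$stack)
  suit <- region_suitability(surf)
  expect_false("desert" %in% suit$region)  # fully masked region excluded
  expect_equal(sum(suit$best), 1)
  expect_equal(suit$region[suit$best], suit$region[which.max(suit$value)])
  # the generator's truth is monotone in var01, so the best region must be
  # the one with the highest mean truth over unmasked cells
  truth_by_region <- surf |>
    dplyr::filter(mask_reason == "ok") |>
    dplyr::mutate(v = w$stack$values[, , 1][cbind(row, col)]) |>
    dplyr::group_by(region) |>
    dplyr::summarise(mv = mean(v))
  expect_equal(suit$region[suit$best],
               truth_by_region$region[which.max(truth_by_region$mv)])
  # constant two-region toy: argmax wins
  toy <- surf |>
    dplyr::filter(region %in% suit$region[1:2], mask_reason == "ok") |>
    dplyr::mutate(predicted = ifelse(region == suit$region[1], 900, 1100))
  suit_toy <- region_suitability(toy)
  expect_equal(suit_toy$region[suit_toy$best], suit$region[2])
  # all-masked surface errors
  empty <- surf |> dplyr::mutate(mask_reason = "out_of_range",
                                 predicted = NA_real_)
  expect_error(region_suitability(empty), class = "pdmboost_empty_result")
})
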