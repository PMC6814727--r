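#' Pipeline configuration with validated defaults
#'
#' Collects every tunable of the end-to-end analysis in one declarative
#' object. Defaults encode the emulated study design: a 40 x 40 grid of 21
#' covariates over 6 rectangular regions (five testable plus a desert), 1393
#' households over 5 breeds, biweekly weighings (males to week 20, females
#' to week 72), the standard record filters (50 g, 30 birds, 6 weeks), the
#' three phases (growing 14-19, adult 20-72), P-spline boosting with
#' `nu = 0.1`, 20 knots, df 4, bootstrap early stopping with 25 resamples,
#' and the n > 25 correlation gate. Unknown keys are rejected.
#'
#' @param ... Overrides for any default listed above; see the source for the
#'   full key set.
#' @return A validated list of class `pdm_config`.
#' @export
pdm_config <- function(...) {
  defaults <- list(
    rows = 40, cols = 40, n_vars = 21, n_regions = 6, smoothness = 4,
    nodata_frac = 0.02,
    n_households = 1393,
    breeds = c("horro", "koekoek", "kuroiler", "sasso", "sasso_rir"),
    surface = default_surface_spec(),
    male_weeks = seq(6, 20, by = 2),
    female_weeks = seq(6, 72, by = 2),
    group_size_range = c(3, 25),
    contamination = list(under50 = 40, over30 = 25, under6wk = 40),
    min_weight = 50, max_birds = 30, min_week = 6,
    nu = 0.1, knots = 20, degree = 3, penalty_order = 2, target_df = 4,
    m_max = 100, cv_B = 25, cv_scheme = "bootstrap",
    region_statistic = "mean", gate_n = 25,
    seed = 1
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "pdmboost_configuration_error")
  }
  cfg <- utils::modifyList(defaults, overrides)
  if (length(cfg$breeds) == 0) {
    abort("`breeds` must be nonempty", class = "pdmboost_configuration_error")
  }
  if (cfg$min_weight <= 0 || cfg$max_birds <= 0 || cfg$min_week <= 0) {
    abort("filter thresholds must be positive", class = "pdmboost_configuration_error")
  }
  if (cfg$n_households < 1) {
    abort("`n_households` must be >= 1", class = "pdmboost_configuration_error")
  }
  structure(cfg, class = "pdm_config")
}

#' Run the full phenotype-distribution-model pipeline
#'
#' Executes simulate, clean, LSmeans, per-model boosting with early
#' stopping, spatial prediction with range masking, region suitability and
#' precision evaluation, writing every intermediate artifact plus a manifest
#' (config hash, seed, per-file MD5) to `out_dir`. Every numeric artifact is
#' reproducible from the config and its seed alone: rerunning with the same
#' config yields byte-identical files.
#'
#' One independent model is fitted per breed and phase; each model gets its
#' own stopping iteration from resampled out-of-bag risk and its own
#' environmental-range mask computed from its training households.
#'
#' @param config A [pdm_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the key tibbles (`lsmeans`, `models`,
#'   `importance`, `suitability`, `reports`, `summary`) and `out_dir`.
#' @export
run_pipeline <- function(config = pdm_config(), out_dir) {
  stopifnot(inherits(config, "pdm_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "pdmboost_stage_error", parent = e)
    })
  }

  # --- simulate -----------------------------------------------------------
  sim <- stage("simulate", {
    stack <- sim_env_stack(config$rows, config$cols, config$n_vars,
                           config$n_regions, config$smoothness,
                           config$nodata_frac, seed = config$seed)
    households <- sim_households(stack, config$n_households, config$breeds,
                                 seed = config$seed + 1)
    weights <- sim_weight_records(
      households, stack, spec = config$surface,
      phase_weeks = list(male = config$male_weeks, female = config$female_weeks),
      group_size_range = config$group_size_range,
      contamination = config$contamination,
      seed = config$seed + 2
    )
    write_env_stack(stack, file.path(out_dir, "stack.json"))
    readr::write_csv(households, file.path(out_dir, "households.csv"))
    write_weight_records(weights$records, file.path(out_dir, "records.csv"))
    readr::write_csv(weights$truth_log, file.path(out_dir, "truth_log.csv"))
    list(stack = stack, households = households, weights = weights)
  })

  # --- clean --------------------------------------------------------------
  cleaned <- stage("clean", {
    avg <- to_average_weight(sim$weights$records)
    res <- apply_weight_filters(avg, min_weight = config$min_weight,
                                max_birds = config$max_birds,
                                min_week = config$min_week)
    readr::write_csv(res$kept, file.path(out_dir, "cleaned.csv"))
    readr::write_csv(res$log, file.path(out_dir, "removal_log.csv"))
    res
  })

  # --- lsmeans ------------------------------------------------------------
  lsm <- stage("lsmeans", {
    phases <- phase_specs()
    out <- purrr::pmap(phases, function(phase, sex, week_lo, week_hi) {
      ph <- phases[phases$phase == phase, ]
      recs <- split_phase(cleaned$kept, ph)
      if (nrow(recs) == 0) return(NULL)
      ew <- phase_average_week(recs)  # pooled over breeds
      recs |>
        group_by(.data$breed) |>
        group_split() |>
        purrr::map(function(d) {
          lsmeans_at_week(fit_household_growth(d), ew, phase = phase)
        }) |>
        list_rbind()
    }) |> list_rbind()
    readr::write_csv(out, file.path(out_dir, "lsmeans.csv"))
    out
  })

  # --- fit / predict / evaluate per breed x phase -------------------------
  covs <- extract_covariates(sim$stack, sim$households)
  model_dir <- file.path(out_dir, "models")
  dir.create(model_dir, showWarnings = FALSE)
  groups <- lsm |> distinct(.data$breed, .data$phase) |> arrange(.data$breed, .data$phase)

  results <- stage("fit", {
    purrr::pmap(list(groups$breed, groups$phase, seq_len(nrow(groups))),
                function(breed, phase, k) {
      d <- lsm |> filter(.data$breed == !!breed, .data$phase == !!phase)
      model_data <- d |>
        select("household_id", "region", "sex", "lsmean") |>
        inner_join(covs, by = "household_id")
      vars <- setdiff(names(covs), "household_id")
      fit <- boost_gam(model_data[c("lsmean", vars)], "lsmean",
                       nu = config$nu, m_max = config$m_max,
                       knots = config$knots, degree = config$degree,
                       penalty_order = config$penalty_order,
                       target_df = config$target_df)
      cv <- cv_mstop(fit, B = config$cv_B, scheme = config$cv_scheme,
                     seed = config$seed + 100 + k)
      tag <- sprintf("%s_%s", breed, phase)
      write_boost_fit(fit, file.path(model_dir, paste0(tag, ".json")),
                      m = cv$m_stop)
      imp <- variable_importance(fit, m = cv$m_stop)
      readr::write_csv(imp, file.path(model_dir, paste0(tag, "_importance.csv")))
      readr::write_csv(
        tibble(iteration = seq_along(fit$inbag_risk) - 1L,
               inbag_risk = fit$inbag_risk,
               mean_oob_risk = c(cv$mean_risk,
                                 rep(NA_real_, length(fit$inbag_risk) -
                                       length(cv$mean_risk)))),
        file.path(model_dir, paste0(tag, "_risk.csv")))

      surf <- predict_surface(fit, sim$stack, m = cv$m_stop, breed = breed,
                              sex = unique(d$sex)[1], phase = phase)
      readr::write_csv(surf, file.path(model_dir, paste0(tag, "_surface.csv")))
      suit <- region_suitability(surf, statistic = config$region_statistic)
      report <- predicted_vs_lsmeans(fit, d, covs, gate_n = config$gate_n,
                                     m = cv$m_stop)
      list(breed = breed, phase = phase, fit = fit, cv = cv, imp = imp,
           suit = suit, report = report)
    })
  })

  suitability <- purrr::map(results, function(rr) {
    rr$suit |> mutate(breed = rr$breed, phase = rr$phase, .before = 1)
  }) |> list_rbind()
  readr::write_csv(suitability, file.path(out_dir, "suitability.csv"))

  importance <- purrr::map(results, function(rr) {
    rr$imp |> mutate(breed = rr$breed, phase = rr$phase, .before = 1)
  }) |> list_rbind()
  readr::write_csv(importance, file.path(out_dir, "importance.csv"))

  reports <- purrr::map(results, function(rr) {
    rr$report |> mutate(breed = rr$breed, phase = rr$phase, .before = 1)
  }) |> list_rbind()
  readr::write_csv(reports, file.path(out_dir, "correlation_report.csv"))

  summary_row <- summarize_report(reports)
  models <- purrr::map(results, function(rr) {
    tibble(breed = rr$breed, phase = rr$phase, m_stop = rr$cv$m_stop,
           top_variable = if (nrow(rr$imp)) rr$imp$variable[1] else NA_character_,
           best_region = rr$suit$region[rr$suit$best])
  }) |> list_rbind()
  readr::write_csv(models, file.path(out_dir, "models.csv"))
  jsonlite::write_json(as.list(summary_row), file.path(out_dir, "summary.json"),
                       digits = NA, auto_unbox = TRUE)

  # --- manifest -----------------------------------------------------------
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE), "manifest.json"))
  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    files = as.list(setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(lsmeans = lsm, models = models, importance = importance,
                 suitability = suitability, reports = reports,
                 summary = summary_row, out_dir = out_dir))
}
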