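#' Specify the true additive response surface of the simulator
#'
#' Defines the ground truth used by [sim_weight_records()]: which covariates
#' actually drive body weight, through which smooth component functions, and
#' the variance components of the growth process. The simulated growth model
#' is a straight line per household through a common hatch weight,
#' `mu_hw = intercept + s_h * w`, with the household slope
#' `s_h = slope_mean_breed + dev_h + (sum_j f_j(x_hj) + b_h) / week_ref`,
#' `dev_h ~ N(0, slope_sd)` and `b_h ~ N(0, household_sd)`. Environmental and
#' household effects therefore act on the growth rate, and at the reference
#' week their contribution in grams equals `sum_j f_j(x_hj) + b_h` exactly;
#' because the truth lies in the common-intercept/household-slope family that
#' the analysis fits, noise-free least-squares means recover it exactly.
#'
#' @param active_vars Character vector of covariates with a real effect.
#' @param component_functions Named list (one per active variable) of
#'   functions of the raw covariate value returning grams at the reference
#'   week.
#' @param intercept Common hatch weight in grams (default 40).
#' @param household_sd SD of the household effect in grams at the reference
#'   week (default 80).
#' @param residual_sd SD of the weighing noise on the mean individual weight,
#'   grams (default 50).
#' @param slope_mean Mean growth rate, grams/week; either a scalar or a named
#'   vector by breed (default 55).
#' @param slope_sd SD of the household growth-rate deviation, grams/week
#'   (default 8).
#' @param week_ref Reference week at which covariate effects are expressed in
#'   grams (default 16.5, the middle of the growing phase).
#' @return An object of class `surface_spec`.
#' @export
surface_spec <- function(active_vars, component_functions,
                         intercept = 40, household_sd = 80, residual_sd = 50,
                         slope_mean = 55, slope_sd = 8, week_ref = 16.5) {
  if (length(active_vars) < 1) abort_invalid("`active_vars` must be nonempty")
  if (!setequal(names(component_functions), active_vars)) {
    abort_invalid("`component_functions` must be named exactly by `active_vars`")
  }
  if (household_sd < 0 || residual_sd < 0 || slope_sd < 0) {
    abort_invalid("standard deviations must be >= 0")
  }
  structure(
    list(active_vars = active_vars,
         component_functions = component_functions,
         intercept = intercept, household_sd = household_sd,
         residual_sd = residual_sd, slope_mean = slope_mean,
         slope_sd = slope_sd, week_ref = week_ref),
    class = "surface_spec"
  )
}

# scale a raw covariate to [0, 1] over its plausible range
scaled01 <- function(x, lo, hi) (x - lo) / (hi - lo)

#' Default true surface: three active covariates with distinct smooth effects
#'
#' Annual mean temperature acts through a sine arc (0 to 300 g at the
#' reference week), annual precipitation through a quadratic bump (0 to
#' 250 g), elevation through a declining logistic (+/- 120 g). The resulting
#' environmental spread of a few hundred grams matches the within-breed
#' range of household means observed in scavenging chicken data.
#'
#' @inheritParams surface_spec
#' @return A `surface_spec`.
#' @export
default_surface_spec <- function(household_sd = 80, residual_sd = 50,
                                 slope_sd = 8, week_ref = 16.5) {
  fns <- list(
    bio01 = function(x) {
      z <- scaled01(x, 5, 30); 300 * sin(pi * z)
    },
    bio12 = function(x) {
      z <- scaled01(x, 100, 2000); 250 * (1 - 4 * (z - 0.5)^2)
    },
    elevation = function(x) {
      z <- scaled01(x, 0, 3500); 120 - 240 / (1 + exp(-8 * (z - 0.5)))
    }
  )
  surface_spec(
    active_vars = names(fns), component_functions = fns,
    intercept = 40,
    slope_mean = c(horro = 48, koekoek = 58, kuroiler = 57,
                   sasso = 62, sasso_rir = 60),
    household_sd = household_sd, residual_sd = residual_sd,
    slope_sd = slope_sd, week_ref = week_ref
  )
}

# per-breed mean slope lookup; scalar applies to every breed
slope_mean_for <- function(spec, breed) {
  sm <- spec$slope_mean
  if (is.null(names(sm))) return(rep(sm[1], length(breed)))
  out <- unname(sm[breed])
  out[is.na(out)] <- mean(sm)
  out
}

# total covariate contribution (grams at week_ref) per household
surface_effect <- function(spec, covariates) {
  eff <- rep(0, nrow(covariates))
  for (v in spec$active_vars) {
    if (!v %in% names(covariates)) {
      abort(sprintf("active variable '%s' not found in covariates", v),
            class = "pdmboost_schema_error")
    }
    eff <- eff + spec$component_functions[[v]](covariates[[v]])
  }
  eff
}

#' Simulate biweekly group weight records, optionally contaminated
#'
#' For every household and sex, draws biweekly group weighings: the group
#' weight is `n_birds * (mu_hw + eps)` with `mu_hw` the household's true
#' growth line (see [surface_spec()]), `eps ~ N(0, residual_sd)` the weighing
#' noise on the mean individual weight, and `n_birds` drawn uniformly from
#' `group_size_range` (default 3-25, emulating roughly 25 delivered chicks
#' with attrition). Noise-free implied average weights below 50 g cannot
#' occur (growth lines start at the hatch weight and weeks start at 6);
#' noisy draws are floored at 50 g so that only injected contamination
#' triggers the under-50 g filter.
#'
#' Contamination, when requested, injects exactly the configured numbers of
#' (i) records whose implied average weight is below 50 g, (ii) households
#' reporting more than 30 birds (one inflated record marks the household;
#' the cleaning filter then drops all its records), and (iii) records at age
#' below 6 weeks. Every injected record/household is flagged in the returned
#' truth log so cleaning can be audited record by record.
#'
#' @param households Tibble from [sim_households()].
#' @param stack The `env_stack` the households live on.
#' @param spec A [surface_spec()]; default [default_surface_spec()].
#' @param phase_weeks Named list of integer weeks (>= 6) at which each sex is
#'   weighed; default biweekly, males to week 20, females to week 72.
#' @param group_size_range Length-2 integer range for birds per weighing.
#' @param contamination List with counts `under50`, `over30`, `under6wk`
#'   (default all 0).
#' @param seed Integer seed.
#' @return A list of class `sim_weights`: `records` (tibble with
#'   `record_id`, `household_id`, `breed`, `sex`, `region`, `lon`, `lat`,
#'   `week`, `group_weight_g`, `n_birds`), `truth_log` (`record_id`,
#'   `household_id`, `class` in clean/under50/over30birds/under6wk),
#'   `effects` (per-household true intercept and slope), and `spec`.
#' @export
sim_weight_records <- function(households, stack, spec = default_surface_spec(),
                               phase_weeks = list(male = seq(6, 20, by = 2),
                                                  female = seq(6, 72, by = 2)),
                               group_size_range = c(3, 25),
                               contamination = list(under50 = 0, over30 = 0,
                                                    under6wk = 0),
                               seed = NULL) {
  if (!is.data.frame(households) || nrow(households) == 0) {
    abort_invalid("`households` must be a nonempty data frame")
  }
  stopifnot(inherits(spec, "surface_spec"))
  wk_all <- unlist(phase_weeks)
  if (any(wk_all < 6)) abort_invalid("`phase_weeks` must all be >= 6")
  n_under50 <- contamination$under50 %||% 0
  n_over30 <- contamination$over30 %||% 0
  n_under6 <- contamination$under6wk %||% 0

  covs <- extract_covariates(stack, households)
  eff <- surface_effect(spec, covs)
  H <- nrow(households)

  with_seed(seed, {
    b_h <- rnorm(H, 0, spec$household_sd)
    dev_h <- rnorm(H, 0, spec$slope_sd)
    slope <- slope_mean_for(spec, households$breed) + dev_h +
      (eff + b_h) / spec$week_ref
    effects <- tibble(
      household_id = households$household_id,
      breed = households$breed,
      intercept = spec$intercept,
      slope = slope,
      env_effect = eff,
      household_effect = b_h
    )

    # clean records: both sexes per household at their phase weeks
    recs <- purrr::map(names(phase_weeks), function(sx) {
      wk <- phase_weeks[[sx]]
      idx <- rep(seq_len(H), each = length(wk))
      tibble(
        household_id = households$household_id[idx],
        breed = households$breed[idx],
        sex = sx,
        region = households$region[idx],
        lon = households$lon[idx],
        lat = households$lat[idx],
        week = rep(wk, times = H),
        mu = spec$intercept + slope[idx] * rep(wk, times = H)
      )
    }) |> list_rbind()
    n_rec <- nrow(recs)
    recs$n_birds <- sample(seq(group_size_range[1], group_size_range[2]),
                           n_rec, replace = TRUE)
    avg <- pmax(recs$mu + rnorm(n_rec, 0, spec$residual_sd), 50)
    recs$group_weight_g <- recs$n_birds * avg
    recs$mu <- NULL
    recs$class <- "clean"

    # contamination: classes kept disjoint by household so the cleaning
    # filters' first-match dispositions coincide with the truth log
    if (n_over30 > 0) {
      if (n_over30 > H) abort_invalid("`over30` exceeds the number of households")
      hh_over <- sample(households$household_id, n_over30)
      for (hh in hh_over) {
        i <- which(recs$household_id == hh)[1]
        avg_i <- recs$group_weight_g[i] / recs$n_birds[i]
        recs$n_birds[i] <- sample(31:40, 1)
        recs$group_weight_g[i] <- recs$n_birds[i] * avg_i
      }
      recs$class[recs$household_id %in% hh_over] <- "over30birds"
    } else {
      hh_over <- character()
    }
    clean_hh <- setdiff(households$household_id, hh_over)
    inject <- function(n, weeks, avg_fun, cls) {
      if (n == 0) return(NULL)
      hh <- sample(clean_hh, n, replace = TRUE)
      m <- match(hh, households$household_id)
      nb <- sample(seq(group_size_range[1], group_size_range[2]), n,
                   replace = TRUE)
      a <- avg_fun(n, m)
      tibble(
        household_id = hh, breed = households$breed[m], sex = "female",
        region = households$region[m], lon = households$lon[m],
        lat = households$lat[m],
        week = sample(weeks, n, replace = TRUE),
        n_birds = nb, group_weight_g = nb * a, class = cls
      )
    }
    bad50 <- inject(n_under50, weeks = wk_all,
                    avg_fun = function(n, m) runif(n, 5, 49.5),
                    cls = "under50")
    bad6 <- inject(n_under6, weeks = c(2, 4),
                   avg_fun = function(n, m) {
                     pmax(spec$intercept + slope[m] * 4 +
                            rnorm(n, 0, spec$residual_sd), 50)
                   },
                   cls = "under6wk")
    recs <- bind_rows(recs, bad50, bad6)
    recs$record_id <- seq_len(nrow(recs))
    truth_log <- recs |> select("record_id", "household_id", "class")
    records <- recs |>
      select("record_id", "household_id", "breed", "sex", "region",
             "lon", "lat", "week", "group_weight_g", "n_birds")

    structure(list(records = records, truth_log = truth_log,
                   effects = effects, spec = spec),
              class = "sim_weights")
  })
}

#' True mean individual weight of simulated households at a given week
#'
#' Evaluates the simulator's ground-truth growth line
#' `intercept + slope_h * week` for each household, e.g. to compare
#' recovered least-squares means against the truth.
#'
#' @param sim A `sim_weights` object.
#' @param week Week (scalar or one per household).
#' @return A tibble: `household_id`, `breed`, `true_weight`.
#' @export
true_weight <- function(sim, week) {
  stopifnot(inherits(sim, "sim_weights"))
  tibble(
    household_id = sim$effects$household_id,
    breed = sim$effects$breed,
    true_weight = sim$effects$intercept + sim$effects$slope * week
  )
}

#' @export
print.sim_weights <- function(x, ...) {
  cat(sprintf("Simulated weight records: %d records, %d households\n",
              nrow(x$records), nrow(x$effects)))
  tab <- table(x$truth_log$class)
  cat("  truth log:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
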