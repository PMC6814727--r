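#' Convert group weighings to average individual weights
#'
#' Each biweekly record weighs all birds of a household together; the
#' per-bird average is the exact quotient `group_weight_g / n_birds`, with no
#' rounding. Records with a nonpositive bird count are invalid.
#'
#' @param records Data frame with at least `group_weight_g` and `n_birds`.
#' @return The input as a tibble with an added `avg_weight_g` column and a
#'   `record_id` column (added if absent).
#' @export
to_average_weight <- function(records) {
  check_columns(records, c("group_weight_g", "n_birds"), "`records`")
  if (any(records$n_birds < 1)) {
    abort("records with n_birds < 1 are invalid", class = "pdmboost_invalid_record")
  }
  out <- as_tibble(records)
  if (!"record_id" %in% names(out)) out$record_id <- seq_len(nrow(out))
  out$avg_weight_g <- out$group_weight_g / out$n_birds
  out
}

#' Apply the three standard record filters
#'
#' Removes, in order: (1) observations with average individual weight below
#' 50 g; (2) all records of any household whose maximum reported bird count
#' exceeds 30; (3) observations at ages below 6 weeks. All boundaries are
#' strict: exactly 50 g, exactly 30 birds, and exactly week 6 are kept. Each
#' record receives exactly one disposition, attributed to the first matching
#' rule, so kept + removed counts always partition the input; the kept set
#' itself does not depend on the rule order because the rules are independent
#' predicates.
#'
#' @param records Tibble from [to_average_weight()] (needs `avg_weight_g`,
#'   `week`, `household_id`, and `n_birds` unless `bird_counts` is given).
#' @param bird_counts Optional data frame `household_id`, `max_n_birds`
#'   giving each household's maximum reported bird count; defaults to the
#'   maximum of `n_birds` within `records`.
#' @param min_weight,max_birds,min_week Filter thresholds (defaults 50 g,
#'   30 birds, 6 weeks).
#' @return A list with `kept` (tibble of surviving records, input order
#'   preserved) and `log` (tibble `record_id`, `household_id`, `disposition`
#'   in kept/removed_under50/removed_over30birds/removed_under6wk).
#' @export
apply_weight_filters <- function(records, bird_counts = NULL,
                                 min_weight = 50, max_birds = 30,
                                 min_week = 6) {
  if (nrow(records) == 0) {
    return(list(kept = as_tibble(records),
                log = tibble(record_id = integer(), household_id = character(),
                             disposition = character())))
  }
  check_columns(records, c("avg_weight_g", "week", "household_id"), "`records`")
  if (is.null(bird_counts)) {
    check_columns(records, "n_birds", "`records`")
    bird_counts <- records |>
      group_by(.data$household_id) |>
      summarise(max_n_birds = max(.data$n_birds), .groups = "drop")
  }
  hh_over <- bird_counts$household_id[bird_counts$max_n_birds > max_birds]

  disposition <- dplyr::case_when(
    records$avg_weight_g < min_weight ~ "removed_under50",
    records$household_id %in% hh_over ~ "removed_over30birds",
    records$week < min_week ~ "removed_under6wk",
    TRUE ~ "kept"
  )
  log <- tibble(
    record_id = records$record_id %||% seq_len(nrow(records)),
    household_id = records$household_id,
    disposition = disposition
  )
  list(kept = as_tibble(records)[disposition == "kept", , drop = FALSE],
       log = log)
}

#' The three age-phase definitions
#'
#' Males are analyzed over the growing phase only (they are typically sold
#' around 20 weeks); females over the growing and the adult phase. Bounds are
#' inclusive at both ends.
#'
#' @return A tibble: `phase`, `sex`, `week_lo`, `week_hi` with rows
#'   male_growing (14-19), female_growing (14-19), female_adult (20-72).
#' @export
phase_specs <- function() {
  tibble(
    phase = c("male_growing", "female_growing", "female_adult"),
    sex = c("male", "female", "female"),
    week_lo = c(14, 14, 20),
    week_hi = c(19, 19, 72)
  )
}

#' Subset records to one age phase
#'
#' Keeps records whose sex matches the phase and whose week lies in the
#' phase's inclusive week window.
#'
#' @param records Tibble with `sex` and `week` columns.
#' @param phase Phase name (one of [phase_specs()]'s `phase` values) or a
#'   one-row data frame with the same columns.
#' @return The matching records (tibble).
#' @export
split_phase <- function(records, phase) {
  if (is.character(phase)) {
    specs <- phase_specs()
    if (!phase %in% specs$phase) {
      abort(sprintf("unknown phase '%s'", phase),
            class = "pdmboost_configuration_error")
    }
    phase <- specs[specs$phase == phase, ]
  }
  check_columns(records, c("sex", "week"), "`records`")
  as_tibble(records) |>
    filter(.data$sex == phase$sex,
           .data$week >= phase$week_lo,
           .data$week <= phase$week_hi)
}

#' Average week of a phase dataset
#'
#' The arithmetic mean of the `week` field over all records of the phase
#' (all breeds pooled): the single week at which every household's
#' least-squares mean is evaluated, so that households with data at
#' different weeks are compared on a common footing.
#'
#' @param records Nonempty tibble with a `week` column.
#' @return The mean week (scalar).
#' @export
phase_average_week <- function(records) {
  check_columns(records, "week", "`records`")
  if (nrow(records) == 0) {
    abort("cannot average weeks of an empty phase dataset",
          class = "pdmboost_empty_dataset")
  }
  mean(records$week)
}
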