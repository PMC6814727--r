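#' Simulate georeferenced households with one breed each
#'
#' Places households uniformly at random over the eligible cells of the
#' environmental grid (non-desert, non-nodata) and assigns breeds round-robin
#' after a seeded shuffle, so that per-breed counts differ by at most one and
#' every breed is spread over the whole testable area. Each household tests
#' exactly one breed, matching the on-farm testing design the simulator
#' emulates.
#'
#' @param stack An `env_stack` from [sim_env_stack()].
#' @param n_households Number of households (>= 1; the emulated program
#'   placed 1393).
#' @param breeds Character vector of breed names (nonempty).
#' @param seed Integer seed.
#' @return A tibble: `household_id`, `breed`, `row`, `col`, `lon`, `lat`,
#'   `region`.
#' @export
sim_households <- function(stack, n_households, breeds, seed = NULL) {
  stopifnot(inherits(stack, "env_stack"))
  if (n_households < 1) abort_invalid("`n_households` must be >= 1")
  if (length(breeds) < 1) abort_invalid("`breeds` must be nonempty")

  eligible <- which(!stack$nodata &
                      stack$region != (stack$desert_region %||% ""))
  if (length(eligible) == 0) {
    abort("no eligible (non-desert, non-nodata) cells to place households on",
          class = "pdmboost_configuration_error")
  }

  with_seed(seed, {
    cells <- sample(eligible, n_households, replace = n_households > length(eligible))
    rc <- arrayInd(cells, dim(stack$region))
    breed_seq <- rep_len(sample(breeds), n_households)
    tibble(
      household_id = sprintf("hh%05d", seq_len(n_households)),
      breed = breed_seq,
      row = rc[, 1],
      col = rc[, 2],
      lon = cell_lon(stack, rc[, 2]),
      lat = cell_lat(stack, rc[, 1]),
      region = stack$region[cells]
    )
  })
}
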