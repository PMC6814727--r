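# internal helpers

# seeded evaluation that leaves the caller's RNG state untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# argument checks raise classed conditions so callers/tests can target them
abort_invalid <- function(msg, class = "pdmboost_invalid_argument") {
  abort(msg, class = class)
}

check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(
      sprintf("%s is missing required column(s): %s", what,
              paste(missing, collapse = ", ")),
      class = "pdmboost_schema_error"
    )
  }
  invisible(df)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
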