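# Readers and writers. Records, LSmeans and reports travel as CSV; the
# environmental stack and fitted models travel as JSON containers written
# losslessly (full double precision).

records_schema <- c("household_id", "breed", "sex", "region", "lon", "lat",
                    "week", "group_weight_g", "n_birds")

#' Read group weight records from CSV
#'
#' Expects the documented header (`household_id`, `breed`, `sex`, `region`,
#' `lon`, `lat`, `week`, `group_weight_g`, `n_birds`). Rows whose numeric
#' fields fail to parse are not silently dropped: they are removed from the
#' returned tibble and collected, with their line numbers, into a tibble
#' attached as attribute `"problems"` (a warning reports the count).
#'
#' @param path CSV file path.
#' @return A tibble of records (with a `record_id` column numbering the
#'   input rows).
#' @export
read_weight_records <- function(path) {
  if (!file.exists(path)) abort_invalid(sprintf("no such file: %s", path))
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character())
  ))
  if (nrow(raw) == 0 && ncol(raw) == 0) {
    abort("empty records file", class = "pdmboost_empty_input")
  }
  check_columns(raw, records_schema, sprintf("records file '%s'", path))
  if (nrow(raw) == 0) {
    warn("records file contains a header but no rows")
  }
  numeric_cols <- c("lon", "lat", "week", "group_weight_g", "n_birds")
  parsed <- raw
  bad <- tibble(line = integer(), column = character(), value = character())
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    is_bad <- is.na(v) & !is.na(raw[[col]])
    if (any(is_bad)) {
      bad <- bind_rows(bad, tibble(line = which(is_bad) + 1L, column = col,
                                   value = raw[[col]][is_bad]))
    }
    parsed[[col]] <- v
  }
  keep <- !(seq_len(nrow(parsed)) %in% (bad$line - 1L))
  out <- parsed[keep, , drop = FALSE]
  out$record_id <- which(keep)
  if (nrow(bad) > 0) {
    warn(sprintf("%d malformed row(s) excluded; see attr(x, 'problems')",
                 length(unique(bad$line))))
  }
  attr(out, "problems") <- bad
  out
}

#' Write group weight records to CSV
#'
#' @param records Tibble with the record schema columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_weight_records <- function(records, path) {
  check_columns(records, records_schema, "`records`")
  readr::write_csv(records[intersect(c("record_id", records_schema),
                                     names(records))], path)
  invisible(path)
}

#' Write an environmental stack to a JSON container
#'
#' Serializes every layer, the region labels, the nodata mask and the grid
#' metadata into one portable JSON file at full double precision, so a
#' write-read round trip is lossless.
#'
#' @param stack An `env_stack`.
#' @param path Output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
write_env_stack <- function(stack, path) {
  stopifnot(inherits(stack, "env_stack"))
  # layers, regions and the mask travel as flat column-major vectors so the
  # reconstruction is unambiguous regardless of JSON simplification rules
  obj <- list(
    var_names = stack$var_names,
    dims = dim(stack$values),
    layers = lapply(seq_along(stack$var_names),
                    function(j) as.vector(stack$values[, , j])),
    region = as.vector(stack$region),
    nodata = as.vector(stack$nodata),
    origin = unname(stack$origin),
    cell_size = stack$cell_size,
    desert_region = stack$desert_region
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = FALSE)
  invisible(path)
}

#' Read an environmental stack from its JSON container
#'
#' @param path File written by [write_env_stack()].
#' @param vars Optional character vector of layers the caller requires; a
#'   missing layer raises a schema error.
#' @return An `env_stack`.
#' @export
read_env_stack <- function(path, vars = NULL) {
  if (!file.exists(path)) abort_invalid(sprintf("no such file: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- obj$dims
  values <- array(NA_real_, dim = d)
  layer_vec <- function(j) {
    if (is.matrix(obj$layers)) obj$layers[j, ] else unlist(obj$layers[[j]])
  }
  for (j in seq_len(d[3])) values[, , j] <- matrix(layer_vec(j), d[1], d[2])
  if (!is.null(vars)) {
    missing <- setdiff(vars, obj$var_names)
    if (length(missing)) {
      abort(sprintf("stack file is missing layer(s): %s",
                    paste(missing, collapse = ", ")),
            class = "pdmboost_schema_error")
    }
  }
  new_env_stack(values, obj$var_names,
                region = matrix(obj$region, d[1], d[2]),
                nodata = matrix(obj$nodata, d[1], d[2]),
                origin = c(lon = obj$origin[1], lat = obj$origin[2]),
                cell_size = obj$cell_size,
                desert_region = obj$desert_region)
}

#' Serialize a boosted model to JSON
#'
#' Writes the offset, per-variable knot vectors and accumulated
#' coefficients, the selection and risk histories and the configuration, at
#' full precision. The stored model predicts at the iteration it was saved
#' at; the in-memory object is the one that supports truncation.
#'
#' @param fit A `boost_fit`.
#' @param path Output path.
#' @param m Iteration at which to freeze the coefficients (default: all run).
#' @return `path`, invisibly.
#' @export
write_boost_fit <- function(fit, path, m = fit$m_stop) {
  stopifnot(inherits(fit, "boost_fit"))
  coef <- coef_at(fit, m)
  obj <- list(
    offset = fit$offset, nu = fit$nu, m = m,
    response = fit$response,
    selection_history = fit$selection_history[seq_len(m)],
    inbag_risk = fit$inbag_risk[seq_len(m + 1)],
    vars = lapply(setNames(fit$vars, fit$vars), function(v) {
      b <- fit$bases[[v]]
      list(knots = b$knots, degree = b$degree,
           penalty_order = b$penalty_order, range = b$range,
           lambda = unname(fit$lambdas[[v]]), coef = coef[[v]])
    })
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialized boosted model
#'
#' @param path File written by [write_boost_fit()].
#' @return A `boost_fit` usable with [predict.boost_fit()] and
#'   [variable_importance()] at its stored iteration.
#' @export
read_boost_fit <- function(path) {
  if (!file.exists(path)) abort_invalid(sprintf("no such file: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vars <- names(obj$vars)
  bases <- lapply(setNames(vars, vars), function(v) {
    b <- obj$vars[[v]]
    structure(
      list(var = v, knots = b$knots, degree = b$degree,
           penalty_order = b$penalty_order, range = b$range,
           dim = length(b$coef)),
      class = "pspline_basis"
    )
  })
  structure(
    list(
      offset = obj$offset, nu = obj$nu, m_stop = obj$m,
      vars = vars, bases = bases,
      lambdas = vapply(obj$vars, function(b) b$lambda, numeric(1)),
      coef = lapply(obj$vars, function(b) b$coef),
      selection_history = as.character(obj$selection_history),
      inbag_risk = obj$inbag_risk,
      steps = NULL, response = obj$response, data = NULL
    ),
    class = "boost_fit"
  )
}
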