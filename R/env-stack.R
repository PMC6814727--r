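# Environmental covariate stack: a regular grid of named covariate layers
# with region labels and a nodata mask. Stored as a plain list of matrices so
# the whole pipeline runs without a geospatial raster dependency; the
# serialized form is a single JSON container (see read_env_stack()).

# the 21 standard covariates: 19 bioclimatic summaries, elevation and the
# fraction of cultivated land, with plausible value ranges used by the
# simulator (temperatures in deg C, precipitation in mm, elevation in m,
# cultivated land in %)
env_var_table <- function() {
  tibble::tribble(
    ~var,          ~lo,   ~hi,
    "bio01",         5,    30,   # annual mean temperature
    "bio02",         5,    20,   # mean diurnal range
    "bio03",        50,   100,   # isothermality
    "bio04",        50,  1000,   # temperature seasonality
    "bio05",        15,    40,   # max temp of warmest month
    "bio06",        -5,    20,   # min temp of coldest month
    "bio07",         5,    35,   # temperature annual range
    "bio08",         5,    30,   # mean temp of wettest quarter
    "bio09",         5,    32,   # mean temp of driest quarter
    "bio10",        10,    35,   # mean temp of warmest quarter
    "bio11",         0,    25,   # mean temp of coldest quarter
    "bio12",       100,  2000,   # annual precipitation
    "bio13",        20,   400,   # precipitation of wettest month
    "bio14",         0,    60,   # precipitation of driest month
    "bio15",        20,   150,   # precipitation seasonality
    "bio16",        50,  1000,   # precipitation of wettest quarter
    "bio17",         0,   150,   # precipitation of driest quarter
    "bio18",        10,   700,   # precipitation of warmest quarter
    "bio19",         0,   500,   # precipitation of coldest quarter
    "elevation",     0,  3500,
    "cultivated",    0,   100
  )
}

new_env_stack <- function(values, var_names, region, nodata, origin, cell_size,
                          desert_region = NULL) {
  stopifnot(length(dim(values)) == 3, dim(values)[3] == length(var_names))
  structure(
    list(values = values, var_names = var_names, region = region,
         nodata = nodata, origin = origin, cell_size = cell_size,
         desert_region = desert_region),
    class = "env_stack"
  )
}

#' @export
print.env_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Environmental stack: %d x %d cells, %d layers\n", d[1], d[2], d[3]))
  cat("  layers:", paste(head(x$var_names, 6), collapse = ", "),
      if (d[3] > 6) "...", "\n")
  regs <- sort(unique(x$region[!x$nodata]))
  cat("  regions:", paste(regs, collapse = ", "), "\n")
  if (!is.null(x$desert_region)) cat("  desert region:", x$desert_region, "\n")
  cat(sprintf("  nodata cells: %d\n", sum(x$nodata)))
  invisible(x)
}

#' Convert an environmental stack to a tibble of cells
#'
#' One row per grid cell with coordinates, region label, nodata flag and one
#' column per covariate layer.
#'
#' @param x An `env_stack`.
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `lon`, `lat`, `region`,
#'   `nodata`, and the covariate layers.
#' @method as_tibble env_stack
#' @export
as_tibble.env_stack <- function(x, ...) {
  d <- dim(x$values)
  cells <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]),
                       KEEP.OUT.ATTRS = FALSE)
  out <- tibble(
    row = cells$row, col = cells$col,
    lon = cell_lon(x, cells$col), lat = cell_lat(x, cells$row),
    region = x$region[cbind(cells$row, cells$col)],
    nodata = x$nodata[cbind(cells$row, cells$col)]
  )
  for (j in seq_along(x$var_names)) {
    out[[x$var_names[j]]] <- x$values[, , j][cbind(cells$row, cells$col)]
  }
  out
}

# coordinate convention: row 1 = northernmost, cell-center referencing,
# longitude increasing with column
cell_lon <- function(stack, col) stack$origin[1] + (col - 1) * stack$cell_size
cell_lat <- function(stack, row) stack$origin[2] - (row - 1) * stack$cell_size

#' Extract covariate rows for georeferenced households
#'
#' Looks up every household's grid cell in the stack and returns its
#' covariate values, ready to be joined with least-squares means as the
#' design matrix of the phenotype distribution model.
#'
#' @param stack An `env_stack`.
#' @param households A data frame with columns `household_id`, `row`, `col`.
#' @return A tibble: `household_id` plus one column per covariate.
#' @export
extract_covariates <- function(stack, households) {
  stopifnot(inherits(stack, "env_stack"))
  check_columns(households, c("household_id", "row", "col"), "`households`")
  idx <- cbind(households$row, households$col)
  out <- tibble(household_id = households$household_id)
  for (j in seq_along(stack$var_names)) {
    out[[stack$var_names[j]]] <- stack$values[, , j][idx]
  }
  out
}
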