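#' Simulate a gridded environmental covariate stack
#'
#' Generates spatially smooth covariate layers by convolving white noise with
#' an isotropic Gaussian kernel of scale `smoothness` and rescaling each
#' layer affinely to a plausible per-variable range (temperatures in deg C,
#' precipitation in mm, elevation in m, cultivated land in %). Regions are
#' contiguous rectangular column blocks; the last region is a designated
#' "desert" whose first covariate layer is shifted strictly above the range
#' observed in every other region, so that environmental-range masking has a
#' region to exclude by construction — mirroring arid zones whose conditions
#' lie outside those under which animals were tested.
#'
#' @param rows,cols Grid dimensions (each >= 4).
#' @param n_vars Number of covariate layers (default 21: the 19 bioclimatic
#'   variables plus elevation and cultivated land).
#' @param n_regions Number of rectangular regions including the desert
#'   (default 6: five testable regions plus the desert).
#' @param smoothness Gaussian kernel scale in cells (> 0, default 3).
#' @param nodata_frac Fraction of cells marked nodata (default 0.02).
#' @param seed Integer seed; identical seeds give bit-identical stacks.
#' @return An `env_stack`.
#' @examples
#' stack <- sim_env_stack(20, 20, n_vars = 5, n_regions = 3, seed = 1)
#' stack
#' @export
sim_env_stack <- function(rows, cols, n_vars = 21, n_regions = 6,
                          smoothness = 3, nodata_frac = 0.02, seed = NULL) {
  if (rows < 4 || cols < 4) abort_invalid("`rows` and `cols` must be >= 4")
  if (n_vars < 1) abort_invalid("`n_vars` must be >= 1")
  if (smoothness <= 0) abort_invalid("`smoothness` must be > 0")
  if (n_regions < 2 || n_regions > cols) {
    abort_invalid("`n_regions` must be between 2 and `cols`")
  }

  ranges <- if (n_vars == 21) {
    env_var_table()
  } else {
    tibble(var = sprintf("var%02d", seq_len(n_vars)), lo = 0, hi = 100)
  }
  var_names <- ranges$var

  with_seed(seed, {
    # column strips -> contiguous rectangular regions; last strip is desert
    breaks <- round(seq(0, cols, length.out = n_regions + 1))
    region_of_col <- rep(seq_len(n_regions), times = diff(breaks))
    region_names <- c(sprintf("R%02d", seq_len(n_regions - 1)), "desert")
    region <- matrix(region_names[region_of_col], nrow = rows, ncol = cols,
                     byrow = TRUE)
    desert <- region == "desert"

    values <- array(NA_real_, dim = c(rows, cols, n_vars))
    for (j in seq_len(n_vars)) {
      f <- smooth_field(rows, cols, smoothness)
      f <- (f - min(f)) / (max(f) - min(f))
      values[, , j] <- ranges$lo[j] + f * (ranges$hi[j] - ranges$lo[j])
    }

    # range-shift layer 1 in the desert so its minimum exceeds the maximum
    # over all other regions
    span <- ranges$hi[1] - ranges$lo[1]
    other_max <- max(values[, , 1][!desert])
    v1 <- values[, , 1]
    v1[desert] <- other_max + 0.05 * span +
      (v1[desert] - min(v1[desert])) * 0.5
    values[, , 1] <- v1

    nodata <- matrix(FALSE, rows, cols)
    n_nodata <- round(nodata_frac * rows * cols)
    if (n_nodata > 0) {
      nodata[sample.int(rows * cols, n_nodata)] <- TRUE
    }

    new_env_stack(values, var_names, region, nodata,
                  origin = c(lon = 36, lat = 14), cell_size = 0.05,
                  desert_region = "desert")
  })
}

# white noise convolved with a separable Gaussian kernel; noise generated on
# an enlarged grid and cropped so edges carry no boundary artifacts
smooth_field <- function(rows, cols, smoothness) {
  half <- max(1L, ceiling(3 * smoothness))
  k <- dnorm(seq(-half, half), sd = smoothness)
  k <- k / sum(k)
  noise <- matrix(rnorm((rows + 2 * half) * (cols + 2 * half)),
                  nrow = rows + 2 * half)
  # convolve rows then columns
  conv1 <- apply(noise, 2, function(v) stats::filter(v, k, sides = 2))
  conv2 <- t(apply(conv1, 1, function(v) stats::filter(v, k, sides = 2)))
  conv2[half + seq_len(rows), half + seq_len(cols)]
}
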