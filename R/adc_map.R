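#' ADC map container
#'
#' @param values 3-D array of diffusion coefficients (mm^2/s); entries at
#'   masked-out voxels are `NA`.
#' @param mask logical 3-D array, `TRUE` where the fit is valid.
#' @param bvals the b-values that produced the map (length 2 for a pairwise
#'   map, longer for a log-linear fit).
#' @param grid a [grid_spec()] matching the source series.
#' @return Object of class `adc_map`.
#' @export
adc_map <- function(values, mask, bvals, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.array(values); mask <- as.array(mask)
  if (!identical(dim(values), dim(mask)))
    stop("values and mask dimensions differ")
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("map dimensions do not match the grid")
  bvals <- as.numeric(bvals)
  if (length(bvals) < 2L || any(diff(bvals) <= 0))
    stop("bvals must be >= 2 strictly increasing values")
  values[!mask] <- NA_real_
  structure(list(values = values, mask = mask, bvals = bvals, grid = grid),
            class = "adc_map")
}

#' @export
print.adc_map <- function(x, ...) {
  cat(sprintf("<adc_map> %s voxels, b = {%s}, %.1f%% valid\n",
              paste(dim(x$values), collapse = " x "),
              paste(x$bvals, collapse = ", "),
              100 * mean(x$mask)))
  invisible(x)
}

#' Two-b-value ADC map
#'
#' The closed-form mono-exponential fit used by scanner consoles:
#' `ADC = ln(S(b_low) / S(b_high)) / (b_high - b_low)`.
#' A voxel is valid only when both signals exceed `signal_floor`; invalid
#' voxels are masked (`NA`), never zero-filled, so they cannot corrupt
#' downstream ROI means. This mirrors how clinical post-processing
#' thresholds away low-intensity voxels.
#'
#' @param series a [dwi_series()].
#' @param b_low,b_high the b-value pair, both present in the series,
#'   `b_high > b_low`.
#' @param signal_floor signal threshold (>= 0, default 0: all strictly
#'   positive signals used).
#' @return An [adc_map()].
#' @export
compute_adc_pair <- function(series, b_low, b_high, signal_floor = 0) {
  stopifnot(inherits(series, "dwi_series"))
  if (signal_floor < 0) stop("signal_floor must be >= 0")
  if (b_high <= b_low) stop("b_high must exceed b_low")
  il <- match(b_low, series$bvals); ih <- match(b_high, series$bvals)
  if (is.na(il) || is.na(ih))
    stop("requested b-values not present in the series")
  dims <- dim(series$signal)[1:3]
  s_lo <- array(series$signal[, , , il], dim = dims)
  s_hi <- array(series$signal[, , , ih], dim = dims)
  mask <- (s_lo > signal_floor) & (s_hi > signal_floor)
  vals <- array(NA_real_, dim = dims)
  vals[mask] <- log(s_lo[mask] / s_hi[mask]) / (b_high - b_low)
  adc_map(vals, mask, c(b_low, b_high), series$grid)
}

#' Multi-b log-linear ADC map
#'
#' Ordinary least-squares fit of `ln S` against `b` over a subset of the
#' series' b-values; the ADC is minus the slope. Voxels with fewer than two
#' signals above `signal_floor` are masked invalid. With exactly two
#' b-values in the subset the result is identical to [compute_adc_pair()].
#'
#' @param series a [dwi_series()].
#' @param b_subset b-values to use (default: all in the series).
#' @param signal_floor signal threshold (>= 0).
#' @return An [adc_map()].
#' @export
compute_adc_loglinear <- function(series, b_subset = NULL, signal_floor = 0) {
  stopifnot(inherits(series, "dwi_series"))
  if (signal_floor < 0) stop("signal_floor must be >= 0")
  if (is.null(b_subset)) b_subset <- series$bvals
  b_subset <- sort(as.numeric(b_subset))
  idx <- match(b_subset, series$bvals)
  if (anyNA(idx)) stop("requested b-values not present in the series")
  if (length(idx) < 2L) stop("need at least 2 b-values")
  if (length(idx) == 2L)
    return(compute_adc_pair(series, b_subset[1], b_subset[2], signal_floor))
  dims <- dim(series$signal)[1:3]
  nvox <- prod(dims)
  S <- matrix(series$signal[, , , idx], nrow = nvox)
  ok <- S > signal_floor
  nok <- rowSums(ok)
  vals <- rep(NA_real_, nvox)
  full <- nok == length(idx)
  if (any(full)) {
    # all points valid: vectorised closed-form OLS slope
    b <- b_subset
    bc <- b - mean(b)
    y <- log(S[full, , drop = FALSE])
    num <- y %*% bc
    vals[full] <- -as.vector(num) / sum(bc^2)
  }
  part <- which(!full & nok >= 2L)
  for (v in part) {
    bi <- b_subset[ok[v, ]]
    yi <- log(S[v, ok[v, ]])
    bc <- bi - mean(bi)
    vals[v] <- -sum(bc * (yi - mean(yi))) / sum(bc^2)
  }
  mask <- nok >= 2L
  dim(vals) <- dims; dim(mask) <- dims
  adc_map(vals, mask, b_subset, series$grid)
}
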