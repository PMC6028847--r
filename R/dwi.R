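#' Construct a diffusion-weighted image series
#'
#' @param signal 4-D array indexed (x, y, z, b-index), non-negative.
#' @param bvals numeric vector of b-values (s/mm^2), non-negative, strictly
#'   increasing, length equal to the 4th dimension.
#' @param grid a [grid_spec()].
#' @param repeat_index integer >= 0 labelling the acquisition repeat.
#' @param label free-text acquisition label.
#' @return Object of class `dwi_series`.
#' @export
dwi_series <- function(signal, bvals, grid, repeat_index = 0L, label = "") {
  stopifnot(inherits(grid, "grid_spec"))
  signal <- as.array(signal)
  if (length(dim(signal)) != 4L)
    stop("signal must be a 4-D array (x, y, z, b)")
  bvals <- as.numeric(bvals)
  if (length(bvals) != dim(signal)[4])
    stop("number of b-values must equal the 4th array dimension")
  if (any(bvals < 0)) stop("b-values must be non-negative")
  if (any(diff(bvals) <= 0)) stop("b-values must be strictly increasing")
  if (!identical(as.integer(dim(signal)[1:3]), grid$shape))
    stop("signal dimensions do not match the grid")
  if (any(signal < 0)) stop("signals must be non-negative")
  structure(list(signal = signal, bvals = bvals, grid = grid,
                 repeat_index = as.integer(repeat_index),
                 label = as.character(label)),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  cat(sprintf("<dwi_series> %s, b = {%s} s/mm^2, repeat %d\n",
              paste(dim(x$signal)[1:3], collapse = " x "),
              paste(x$bvals, collapse = ", "), x$repeat_index))
  invisible(x)
}

#' Apply Rician noise to magnitude values
#'
#' Magnitude-MRI noise: `out = sqrt((v + g1)^2 + g2^2)` with `g1`, `g2`
#' independent zero-mean Gaussians of standard deviation `sigma`.
#' `sigma = 0` returns the input unchanged.
#'
#' @param values numeric vector/array of noiseless magnitudes.
#' @param sigma Gaussian channel SD (signal units), >= 0.
#' @param seed optional integer seed for reproducibility.
#' @return Noisy values, same shape as the input.
#' @export
add_rician_noise <- function(values, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(values)
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  out <- sqrt((values + stats::rnorm(n, 0, sigma))^2 +
              stats::rnorm(n, 0, sigma)^2)
  if (!is.null(dim(values))) dim(out) <- dim(values)
  out
}

#' Synthesise DWI repeats from a rasterised scene
#'
#' The noiseless voxel signal at b-value `b` mixes compartments in the
#' signal domain:
#' `S(b) = sum_c fraction_c * S0_c * exp(-b * ADC_c * (1 + eps(p)))`,
#' where `eps(p)` is the multiplicative bias field evaluated at the voxel
#' centre `p`. Noise (Rician by default, Gaussian optionally for analytic
#' checks) is applied per voxel, per b-value and per repeat; repeats differ
#' only by the noise realisation.
#'
#' @param raster a [rasterize_scene()] result.
#' @param bvals b-values (s/mm^2), strictly increasing, non-negative.
#' @param bias optional [bias_field()].
#' @param noise_sd noise channel SD in signal units (>= 0).
#' @param n_repeats number of repeat acquisitions (>= 1).
#' @param seed integer seed; the same seed reproduces the series exactly.
#' @param noise_model `"rician"` (default) or `"gaussian"` (values floored
#'   at 0 to preserve magnitude non-negativity).
#' @return List of [dwi_series()], one per repeat.
#' @export
synthesize_dwi <- function(raster, bvals, bias = NULL, noise_sd = 0,
                           n_repeats = 1L, seed = NULL,
                           noise_model = c("rician", "gaussian")) {
  stopifnot(inherits(raster, "scene_raster"))
  noise_model <- match.arg(noise_model)
  bvals <- as.numeric(bvals)
  if (any(bvals < 0)) stop("b-values must be non-negative")
  if (any(diff(bvals) <= 0)) stop("b-values must be strictly increasing")
  n_repeats <- as.integer(n_repeats)
  if (n_repeats < 1L) stop("n_repeats must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  g <- raster$grid
  ax <- grid_axes(g)
  nvox <- prod(g$shape)
  pos <- cbind(rep(ax$x, times = g$shape[2] * g$shape[3]),
               rep(rep(ax$y, each = g$shape[1]), times = g$shape[3]),
               rep(ax$z, each = g$shape[1] * g$shape[2]))
  eps <- eval_bias(bias, pos)
  ncomp <- length(raster$s0)
  nb <- length(bvals)
  clean <- array(0, dim = c(g$shape, nb))
  for (ib in seq_len(nb)) {
    sig <- numeric(nvox)
    for (p in seq_len(ncomp)) {
      fr <- as.vector(raster$fractions[, , , p])
      if (all(fr == 0)) next
      sig <- sig + fr * raster$s0[p] *
        exp(-bvals[ib] * raster$adc[p] * (1 + eps))
    }
    clean[, , , ib] <- sig
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    if (noise_sd == 0) {
      noisy <- clean
    } else if (noise_model == "rician") {
      noisy <- add_rician_noise(clean, noise_sd)
    } else {
      noisy <- pmax(clean + stats::rnorm(length(clean), 0, noise_sd), 0)
      dim(noisy) <- dim(clean)
    }
    out[[r]] <- dwi_series(noisy, bvals, g, repeat_index = r - 1L,
                           label = sprintf("repeat %d", r - 1L))
  }
  out
}
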