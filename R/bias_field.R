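#' Multiplicative spatial ADC bias field
#'
#' Models the spatially varying relative ADC error caused by gradient-field
#' non-linearity as a separable polynomial field
#' `eps(x, y, z) = eps_x(x) + eps_y(y) + eps_z(z)`, each axis term a
#' polynomial with zero intercept so that `eps(0, 0, 0) = 0` at the magnet
#' isocentre, where gradients are most linear. The field acts
#' multiplicatively on the true diffusion coefficient:
#' `measured ADC = true ADC * (1 + eps)`.
#'
#' Coefficients are per-axis vectors `c(c1, c2, ...)` for powers 1, 2, ... of
#' the distance in cm; `eps` is a dimensionless fraction.
#'
#' @param coef_x,coef_y,coef_z numeric coefficient vectors (possibly empty).
#' @return Object of class `bias_field`.
#' @examples
#' bf <- bias_field(coef_y = c(0, 0.01))  # eps(y) = 0.01 * (y/cm)^2
#' eval_bias(bf, cbind(0, 40, 0))         # 0.16 at y = 4 cm
#' @export
bias_field <- function(coef_x = numeric(0), coef_y = numeric(0),
                       coef_z = numeric(0)) {
  structure(list(coef = list(x = as.numeric(coef_x), y = as.numeric(coef_y),
                             z = as.numeric(coef_z))),
            class = "bias_field")
}

#' Evaluate a bias field at world positions
#'
#' @param field a [bias_field()] (or `NULL`, treated as zero field).
#' @param xyz_mm numeric matrix (n x 3) of world positions in mm.
#' @return Numeric vector of relative ADC errors (fractions).
#' @export
eval_bias <- function(field, xyz_mm) {
  xyz_mm <- rbind(xyz_mm)
  if (is.null(field)) return(rep(0, nrow(xyz_mm)))
  stopifnot(inherits(field, "bias_field"), ncol(xyz_mm) == 3L)
  eps <- rep(0, nrow(xyz_mm))
  for (k in 1:3) {
    cf <- field$coef[[k]]
    if (length(cf) == 0L) next
    d_cm <- xyz_mm[, k] / 10
    for (p in seq_along(cf)) eps <- eps + cf[p] * d_cm^p
  }
  eps
}

#' Fit a bias field to measured shift profiles
#'
#' Least-squares polynomial fit (zero intercept) of relative ADC error
#' against distance from the isocentre, one profile per axis. This is how a
#' phantom-measured table of shifted-ROI relative errors becomes a smooth
#' field usable in simulation.
#'
#' @param profiles named list (`x`, `y` and/or `z`); each element a
#'   two-column structure (`distance_cm`, `rel_error_pct`). The zero-distance
#'   point with value 0 must be present.
#' @param degree polynomial degree (default 2).
#' @return A [bias_field()].
#' @export
fit_bias_field <- function(profiles, degree = 2L) {
  degree <- as.integer(degree)
  stopifnot(degree >= 1L)
  coefs <- list(x = numeric(0), y = numeric(0), z = numeric(0))
  for (axn in names(profiles)) {
    pr <- profiles[[axn]]
    d <- as.numeric(pr[[1]]); v <- as.numeric(pr[[2]])
    if (length(d) < 3L)
      stop("need at least 3 profile points per fitted axis")
    if (!any(d == 0 & v == 0))
      stop("profile must contain the isocentre point (0, 0)")
    if (length(d) < degree + 1L)
      stop("fewer profile points than polynomial coefficients")
    X <- outer(d, seq_len(degree), `^`)
    fit <- stats::lm.fit(X, v / 100)
    coefs[[axis_name(axn)]] <- unname(fit$coefficients)
  }
  bias_field(coef_x = coefs$x, coef_y = coefs$y, coef_z = coefs$z)
}

axis_name <- function(axis) c("x", "y", "z")[axis_index(axis)]

#' Measured spatial shift profiles of relative ADC error
#'
#' The phantom measurements of relative ADC error (%) versus distance from
#' the isocentre: a flat horizontal (x, rightward) profile out to 18 cm and a
#' strongly increasing vertical (y, downward) profile out to 8 cm.
#'
#' @return Named list of data frames (`x`, `y`) with columns `distance_cm`
#'   and `rel_error_pct`.
#' @export
spatial_shift_profiles <- function() {
  list(
    x = data.frame(
      distance_cm = seq(0, 18, by = 2),
      rel_error_pct = c(0.0, 1.6, -6.3, -5.5, -2.3, -3.9, -1.6, 3.1, -1.6, 0.8)),
    y = data.frame(
      distance_cm = seq(0, 8, by = 2),
      rel_error_pct = c(0.0, -0.9, 9.3, 13.0, 24.1)))
}

#' Default gradient-nonlinearity bias field
#'
#' Quadratic zero-intercept fit to the measured vertical shift profile
#' (0, -0.9, 9.3, 13.0, 24.1 % at 0, 2, 4, 6, 8 cm); the horizontal profile
#' shows no trend and is modelled as exactly zero.
#'
#' @return A [bias_field()].
#' @export
default_bias_field <- function() {
  fit_bias_field(spatial_shift_profiles()["y"], degree = 2L)
}
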