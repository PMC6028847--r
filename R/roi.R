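#' ROI / VOI specification
#'
#' Circular in-plane ROIs and spherical VOIs, specified in world mm.
#' Voxel selection uses strict centre inclusion: a voxel belongs to the ROI
#' iff its centre lies strictly inside the boundary. This rule is
#' deterministic, matches common viewer behaviour, and excludes
#' measure-zero boundary ties for reproducibility across platforms.
#'
#' @param center world coordinate (mm), length 3. For a circle the z
#'   component picks the slice whose centre is nearest.
#' @param diameter_mm ROI diameter (> 0).
#' @return Object of class `roi_spec`.
#' @name roi-spec
NULL

#' @rdname roi-spec
#' @export
roi_circle <- function(center, diameter_mm) {
  new_roi("circle", center, diameter_mm)
}

#' @rdname roi-spec
#' @export
roi_sphere <- function(center, diameter_mm) {
  new_roi("sphere", center, diameter_mm)
}

new_roi <- function(shape, center, diameter_mm) {
  center <- as.numeric(center)
  stopifnot(length(center) == 3L)
  if (diameter_mm <= 0) stop("ROI diameter must be positive")
  structure(list(shape = shape, center = center, diameter_mm = diameter_mm),
            class = "roi_spec")
}

#' Select voxels inside an ROI
#'
#' @param grid a [grid_spec()].
#' @param roi an [roi_spec()].
#' @return Integer vector of linear (column-major) voxel indices into arrays
#'   on `grid`; attribute `n` gives the count.
#' @export
select_voxels <- function(grid, roi) {
  stopifnot(inherits(grid, "grid_spec"), inherits(roi, "roi_spec"))
  ax <- grid_axes(grid)
  r2 <- (roi$diameter_mm / 2)^2
  dx2 <- (ax$x - roi$center[1])^2
  dy2 <- (ax$y - roi$center[2])^2
  if (roi$shape == "circle") {
    zlo <- grid$origin[3]; zhi <- grid$origin[3] + grid$shape[3] * grid$spacing[3]
    if (roi$center[3] < zlo || roi$center[3] > zhi)
      stop("empty ROI: circle plane lies outside the grid")
    iz <- which.min(abs(ax$z - roi$center[3]))
    inplane <- outer(dx2, dy2, `+`) < r2
    idx <- which(inplane) + (iz - 1L) * grid$shape[1] * grid$shape[2]
  } else {
    dz2 <- (ax$z - roi$center[3])^2
    nx <- grid$shape[1]; ny <- grid$shape[2]
    inplane <- outer(dx2, dy2, `+`)
    idx <- integer(0)
    for (iz in seq_len(grid$shape[3])) {
      hit <- which(inplane + dz2[iz] < r2)
      if (length(hit))
        idx <- c(idx, hit + (iz - 1L) * nx * ny)
    }
  }
  if (length(idx) == 0L)
    stop("empty ROI: no voxel centre falls inside the boundary")
  structure(idx, n = length(idx))
}

#' ROI statistics on an ADC map
#'
#' Counts only mask-valid voxels; mean and sample (n-1) standard deviation
#' over those voxels.
#'
#' @param map an [adc_map()] (or a bare 3-D numeric array, treated as fully
#'   valid where finite).
#' @param voxels linear voxel indices from [select_voxels()].
#' @return Object of class `roi_stats`: list(`n`, `mean`, `sd`).
#' @export
roi_statistics <- function(map, voxels) {
  if (inherits(map, "adc_map")) {
    vals <- map$values[voxels]
    vals <- vals[map$mask[voxels]]
  } else {
    vals <- as.array(map)[voxels]
    vals <- vals[is.finite(vals)]
  }
  if (length(vals) == 0L)
    stop("empty ROI: no valid voxels among the selection")
  roi_stats(n = length(vals), mean = mean(vals),
            sd = if (length(vals) > 1L) stats::sd(vals) else 0)
}

roi_stats <- function(n, mean, sd) {
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("<roi_stats> n = %d, mean = %.4g, sd = %.4g\n",
              x$n, x$mean, x$sd))
  invisible(x)
}

#' Across-repeat collection of ROI statistics
#'
#' Holds the per-repeat ROI means of one ROI measured on repeated
#' acquisitions; `mu_R` is the mean of means and `sigma_R` their sample
#' standard deviation — the inputs to the repeatability metrics.
#'
#' @param stats_list list of `roi_stats`, one per repeat (>= 1; >= 2 for a
#'   defined `sigma_R`).
#' @return Object of class `repeat_series`: list(`stats`, `means`, `mu_R`,
#'   `sigma_R`).
#' @export
repeat_series <- function(stats_list) {
  if (inherits(stats_list, "roi_stats")) stats_list <- list(stats_list)
  stopifnot(length(stats_list) >= 1L)
  for (s in stats_list) stopifnot(inherits(s, "roi_stats"))
  means <- vapply(stats_list, `[[`, numeric(1), "mean")
  structure(list(stats = stats_list, means = means,
                 mu_R = mean(means),
                 sigma_R = if (length(means) > 1L) stats::sd(means) else NA_real_),
            class = "repeat_series")
}

#' Shifted-ROI series along an axis
#'
#' Places ROIs of a fixed diameter at increasing distances from a start
#' centre along one axis and reports each ROI's statistics together with the
#' relative deviation (%) of its mean from the distance-0 mean:
#' `100 * (mu_d - mu_0) / mu_0`. ROIs that would leave the grid truncate the
#' series with a warning rather than being silently clipped.
#'
#' @param map an [adc_map()].
#' @param axis shift axis (`"x"` right, `"y"` down).
#' @param step_mm shift increment (mm).
#' @param n_steps number of shifts beyond distance 0.
#' @param diameter_mm ROI diameter (mm).
#' @param center start centre (default isocentre `c(0,0,0)`).
#' @param shape `"circle"` (default, in-plane) or `"sphere"`.
#' @return data.frame with columns `distance_mm`, `distance_cm`, `n`,
#'   `mean`, `sd`, `rel_pct`.
#' @export
shifted_roi_series <- function(map, axis, step_mm, n_steps, diameter_mm,
                               center = c(0, 0, 0),
                               shape = c("circle", "sphere")) {
  stopifnot(inherits(map, "adc_map"))
  shape <- match.arg(shape)
  ax <- axis_index(axis)
  g <- map$grid
  lo <- g$origin; hi <- g$origin + g$shape * g$spacing
  rows <- vector("list", n_steps + 1L)
  for (k in 0:n_steps) {
    ctr <- center
    ctr[ax] <- ctr[ax] + k * step_mm
    r <- diameter_mm / 2
    inside <- if (shape == "circle") {
      all(ctr[1:2] - r >= lo[1:2]) && all(ctr[1:2] + r <= hi[1:2]) &&
        ctr[3] >= lo[3] && ctr[3] <= hi[3]
    } else {
      all(ctr - r >= lo) && all(ctr + r <= hi)
    }
    if (!inside) {
      warning(sprintf(
        "shifted ROI at %g mm leaves the grid; series truncated at %d steps",
        k * step_mm, k - 1L))
      rows <- rows[seq_len(k)]
      break
    }
    roi <- new_roi(shape, ctr, diameter_mm)
    st <- roi_statistics(map, select_voxels(g, roi))
    rows[[k + 1L]] <- data.frame(distance_mm = k * step_mm,
                                 n = st$n, mean = st$mean, sd = st$sd)
  }
  out <- do.call(rbind, rows)
  out$distance_cm <- out$distance_mm / 10
  out$rel_pct <- 100 * (out$mean - out$mean[1]) / out$mean[1]
  out$rel_pct[1] <- 0
  out[, c("distance_mm", "distance_cm", "n", "mean", "sd", "rel_pct")]
}
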