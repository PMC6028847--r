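#' Relative error in percent
#'
#' `100 * (value - reference) / reference` — the arithmetic behind every
#' sphere-phantom relative-error table.
#'
#' @param value measured value(s).
#' @param reference reference value (non-zero).
#' @return Signed relative error(s), %.
#' @export
relative_error_pct <- function(value, reference) {
  if (any(reference == 0)) stop("reference must be non-zero")
  100 * (value - reference) / reference
}

#' VOI diameter rule for sphere measurements
#'
#' The measurement VOI is `fraction` times the physical sphere diameter,
#' floored at `floor_mm` because smaller VOIs are not usefully sampled at
#' clinical voxel sizes (the 10-mm floor corresponds to only ~8 voxels on
#' the clinical grid). The floor never exceeds the sphere diameter.
#'
#' @param sphere_diameter_mm physical sphere diameter.
#' @param fraction VOI-to-sphere diameter ratio (default 0.8).
#' @param floor_mm minimum VOI diameter (default 10).
#' @return VOI diameter (mm).
#' @export
voi_diameter <- function(sphere_diameter_mm, fraction = 0.8, floor_mm = 10) {
  pmin(pmax(fraction * sphere_diameter_mm, floor_mm), sphere_diameter_mm)
}

sphere_center <- function(layout, i) c(layout$cx[i], layout$cy[i], layout$cz[i])

reference_index <- function(layout) {
  which(layout$id == attr(layout, "reference_id"))
}

voi_stats_over_maps <- function(maps, grid, center, diameter_mm) {
  vox <- select_voxels(grid, roi_sphere(center, diameter_mm))
  lapply(maps, roi_statistics, voxels = vox)
}

#' Sphere-size scaling analysis (80% VOIs)
#'
#' For each sphere, measures a VOI of 80% of the sphere's diameter (floored
#' at 10 mm), averages the ROI mean over repeat maps, and reports the
#' relative error versus the largest (reference) sphere plus the
#' coefficient of variation across repeats. Shrinking spheres mix more
#' edge-contaminated voxels into the VOI, so the relative error grows as
#' the sphere shrinks — the partial-volume scaling effect.
#'
#' @param maps list of [adc_map()], one per repeat/day.
#' @param layout a [sphere_layout()].
#' @param voi_fraction VOI-to-sphere diameter ratio (default 0.8).
#' @param voi_floor_mm minimum VOI diameter (default 10 mm).
#' @return data.frame with one row per sphere: `sphere_id`,
#'   `sphere_diameter_mm`, `voi_diameter_mm`, `n_voxels`, `mean_adc`,
#'   `rel_error_pct`, `cv_pct`. A sphere whose VOI selects no voxels is
#'   reported with `NA` values and the analysis continues.
#' @export
scaling_analysis <- function(maps, layout, voi_fraction = 0.8,
                             voi_floor_mm = 10) {
  stopifnot(inherits(layout, "sphere_layout"), length(maps) >= 1L)
  grid <- maps[[1]]$grid
  iref <- reference_index(layout)
  rows <- lapply(seq_len(nrow(layout)), function(i) {
    dvoi <- voi_diameter(layout$diameter_mm[i], voi_fraction, voi_floor_mm)
    st <- tryCatch(
      voi_stats_over_maps(maps, grid, sphere_center(layout, i), dvoi),
      error = function(e) e)
    if (inherits(st, "error")) {
      warning(sprintf("sphere %s: %s", layout$id[i], conditionMessage(st)))
      return(data.frame(sphere_id = layout$id[i],
                        sphere_diameter_mm = layout$diameter_mm[i],
                        voi_diameter_mm = dvoi, n_voxels = NA_integer_,
                        mean_adc = NA_real_, cv_pct = NA_real_,
                        stringsAsFactors = FALSE))
    }
    reps <- repeat_series(st)
    data.frame(sphere_id = layout$id[i],
               sphere_diameter_mm = layout$diameter_mm[i],
               voi_diameter_mm = dvoi, n_voxels = st[[1]]$n,
               mean_adc = reps$mu_R,
               cv_pct = if (length(maps) > 1L) cv_repeatability(reps)
                        else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ref_mean <- out$mean_adc[iref]
  out$rel_error_pct <- relative_error_pct(out$mean_adc, ref_mean)
  out[order(-out$sphere_diameter_mm),
      c("sphere_id", "sphere_diameter_mm", "voi_diameter_mm", "n_voxels",
        "mean_adc", "rel_error_pct", "cv_pct")]
}

#' Concentric-VOI analysis within the reference sphere
#'
#' Measures VOIs of decreasing diameter all centred on the largest sphere.
#' Because every VOI samples the same clean interior, mean deviations stay
#' small; this isolates pure VOI-size effects from the partial-volume
#' contamination probed by [scaling_analysis()].
#'
#' @param map an [adc_map()] (or average map).
#' @param layout a [sphere_layout()].
#' @param voi_diameters_mm VOI diameters, all <= the reference sphere
#'   diameter (default `c(30, 26, 22, 18, 14, 10)`).
#' @return data.frame: `voi_diameter_mm`, `n_voxels`, `mean_adc`, `sd_adc`,
#'   `dev_vs_largest_pct`.
#' @export
concentric_voi_analysis <- function(map, layout,
                                    voi_diameters_mm = c(30, 26, 22, 18, 14, 10)) {
  stopifnot(inherits(map, "adc_map"), inherits(layout, "sphere_layout"))
  iref <- reference_index(layout)
  dref <- layout$diameter_mm[iref]
  if (any(voi_diameters_mm > dref))
    stop("VOI larger than the reference sphere")
  voi_diameters_mm <- sort(voi_diameters_mm, decreasing = TRUE)
  ctr <- sphere_center(layout, iref)
  rows <- lapply(voi_diameters_mm, function(d) {
    st <- roi_statistics(map, select_voxels(map$grid, roi_sphere(ctr, d)))
    data.frame(voi_diameter_mm = d, n_voxels = st$n,
               mean_adc = st$mean, sd_adc = st$sd)
  })
  out <- do.call(rbind, rows)
  out$dev_vs_largest_pct <- relative_error_pct(out$mean_adc, out$mean_adc[1])
  out
}

#' Differential same-size-VOI partial-volume analysis
#'
#' For each non-reference sphere, measures the 80%-rule VOI centred in that
#' sphere AND an identically sized VOI centred in the reference sphere, then
#' reports `|100 * (mean_target - mean_ref) / mean_ref|`. Because both VOIs
#' have the same size and shape, any systematic difference is attributable
#' to partial-volume contamination of the smaller sphere, not to VOI-size
#' effects.
#'
#' @inheritParams scaling_analysis
#' @return data.frame: `pair` (e.g. `"37 vs 28"`), `sphere_diameter_mm`,
#'   `voi_diameter_mm`, `n_voxels`, `mean_adc_ref`, `mean_adc_target`,
#'   `abs_rel_error_pct`.
#' @export
differential_same_size_analysis <- function(maps, layout, voi_fraction = 0.8,
                                            voi_floor_mm = 10) {
  stopifnot(inherits(layout, "sphere_layout"), length(maps) >= 1L)
  grid <- maps[[1]]$grid
  iref <- reference_index(layout)
  dref <- layout$diameter_mm[iref]
  targets <- setdiff(seq_len(nrow(layout)), iref)
  targets <- targets[order(-layout$diameter_mm[targets])]
  rows <- lapply(targets, function(i) {
    dvoi <- voi_diameter(layout$diameter_mm[i], voi_fraction, voi_floor_mm)
    if (dvoi > dref)
      stop("same-size VOI does not fit inside the reference sphere")
    st_t <- voi_stats_over_maps(maps, grid, sphere_center(layout, i), dvoi)
    st_r <- voi_stats_over_maps(maps, grid, sphere_center(layout, iref), dvoi)
    m_t <- repeat_series(st_t)$mu_R
    m_r <- repeat_series(st_r)$mu_R
    data.frame(
      pair = sprintf("%g vs %g", dref, layout$diameter_mm[i]),
      sphere_diameter_mm = layout$diameter_mm[i],
      voi_diameter_mm = dvoi, n_voxels = st_t[[1]]$n,
      mean_adc_ref = m_r, mean_adc_target = m_t,
      abs_rel_error_pct = abs(relative_error_pct(m_t, m_r)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
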