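#' Ice-water phantom quality-control experiment
#'
#' End-to-end run of the accuracy/repeatability protocol: simulate repeated
#' DWI acquisitions of the ice-water phantom at b = 0, 100, 600, 800 s/mm^2,
#' fit the (b0, b100), (b0, b600) and (b0, b800) ADC maps per repeat,
#' measure a circular ROI at the isocentre, and assemble the QC report.
#'
#' @param scene a [phantom_scene()] (default [icewater_scene()]).
#' @param bvals acquisition b-values (default `c(0, 100, 600, 800)`).
#' @param n_repeats repeat acquisitions (default 4).
#' @param noise_sd Rician channel SD in signal units (default 0: noiseless).
#' @param bias optional [bias_field()].
#' @param roi_diameter_mm analysis ROI diameter (default 25).
#' @param thresholds a [qiba_thresholds()].
#' @param seed integer seed.
#' @param supersample rasterisation sub-sampling (default 2; the phantom is
#'   uniform at the ROI so fine edge fractions do not matter here).
#' @return list(`report` ([qc_report()]), `maps` (per-pair lists of
#'   [adc_map()]), `series`, `roi_voxels`).
#' @export
icewater_qc_experiment <- function(scene = icewater_scene(),
                                   bvals = c(0, 100, 600, 800),
                                   n_repeats = 4L, noise_sd = 0,
                                   bias = NULL, roi_diameter_mm = 25,
                                   thresholds = qiba_thresholds(),
                                   seed = NULL, supersample = 2L) {
  raster <- rasterize_scene(scene, supersample = supersample)
  series <- synthesize_dwi(raster, bvals, bias = bias, noise_sd = noise_sd,
                           n_repeats = n_repeats, seed = seed)
  pairs <- setdiff(bvals, min(bvals))
  maps <- lapply(pairs, function(bh) {
    lapply(series, compute_adc_pair, b_low = min(bvals), b_high = bh)
  })
  names(maps) <- paste0("b", pairs)
  vox <- select_voxels(scene$grid, roi_circle(c(0, 0, 0), roi_diameter_mm))
  pair_stats <- lapply(maps, function(ms) lapply(ms, roi_statistics, voxels = vox))
  ib0 <- match(min(bvals), bvals)
  b0_reps <- lapply(series, function(s)
    array(s$signal[, , , ib0], dim = dim(s$signal)[1:3]))
  rep_obj <- qc_report(pair_stats, b0_reps, vox, thresholds)
  list(report = rep_obj, maps = maps, series = series, roi_voxels = vox)
}

#' Sphere-phantom partial-volume experiment
#'
#' Simulates repeat acquisitions of the six-sphere phantom under the
#' clinical protocol (b = 50, 1000 s/mm^2), fits the pairwise ADC map per
#' repeat, and runs the three phantom analyses: the 80%-VOI scaling study,
#' the concentric-VOI study in the largest sphere, and the same-size
#' differential partial-volume study.
#'
#' @param layout a [sphere_layout()].
#' @param scene a [phantom_scene()] built on `layout` (default
#'   [sphere_phantom_scene()]).
#' @param bvals clinical b-values (default `c(50, 1000)`).
#' @param n_repeats repeat acquisitions / days (default 4).
#' @param noise_sd Rician channel SD (default 0).
#' @param seed integer seed.
#' @param voi_fraction,voi_floor_mm VOI rule (defaults 0.8 and 10 mm).
#' @param supersample rasterisation sub-sampling (default 5: edge fractions
#'   drive the partial-volume effect under study).
#' @return list(`scaling`, `concentric`, `differential` data frames,
#'   `maps`, `layout`).
#' @export
sphere_phantom_experiment <- function(layout = sphere_layout(),
                                      scene = sphere_phantom_scene(layout),
                                      bvals = c(50, 1000),
                                      n_repeats = 4L, noise_sd = 0,
                                      seed = NULL, voi_fraction = 0.8,
                                      voi_floor_mm = 10, supersample = 5L) {
  raster <- rasterize_scene(scene, supersample = supersample)
  series <- synthesize_dwi(raster, bvals, noise_sd = noise_sd,
                           n_repeats = n_repeats, seed = seed)
  maps <- lapply(series, compute_adc_pair, b_low = bvals[1], b_high = bvals[2])
  avg_map <- maps[[1]]
  if (length(maps) > 1L) {
    vals <- Reduce(`+`, lapply(maps, function(m) {
      v <- m$values; v[!m$mask] <- 0; v
    })) / length(maps)
    mask <- Reduce(`&`, lapply(maps, `[[`, "mask"))
    vals[!mask] <- NA_real_
    avg_map <- adc_map(vals, mask, avg_map$bvals, avg_map$grid)
  }
  list(
    scaling = scaling_analysis(maps, layout, voi_fraction, voi_floor_mm),
    concentric = concentric_voi_analysis(avg_map, layout),
    differential = differential_same_size_analysis(maps, layout,
                                                   voi_fraction, voi_floor_mm),
    maps = maps, layout = layout)
}

#' Spatial-bias profiling experiment
#'
#' Simulates a noiseless acquisition of a uniform water phantom under a
#' given bias field, fits the ADC map, and profiles the relative ADC error
#' along the horizontal and vertical axes with Pearson correlations —
#' the forward model of the gradient-nonlinearity analysis.
#'
#' @param bias a [bias_field()] (default [default_bias_field()]).
#' @param scene uniform phantom scene (default [icewater_scene()]).
#' @param step_mm,n_steps shift schedule (defaults 20 mm and 4: 0-8 cm).
#' @param roi_diameter_mm profiling ROI diameter (default 8 mm; small ROIs
#'   track the field value at the ROI centre rather than its in-plane
#'   average).
#' @param b_pair the two b-values to acquire and fit (default
#'   `c(0, 800)`).
#' @param axes axes to profile (default `c("x", "y")`).
#' @return Named list of [spatial_profile()] results.
#' @export
bias_profile_experiment <- function(bias = default_bias_field(),
                                    scene = icewater_scene(),
                                    step_mm = 20, n_steps = 4L,
                                    roi_diameter_mm = 8,
                                    b_pair = c(0, 800),
                                    axes = c("x", "y")) {
  raster <- rasterize_scene(scene, supersample = 1L)
  series <- synthesize_dwi(raster, b_pair, bias = bias, noise_sd = 0,
                           n_repeats = 1L)[[1]]
  map <- compute_adc_pair(series, b_pair[1], b_pair[2])
  out <- lapply(axes, function(ax) {
    spatial_profile(map, ax, step_mm, n_steps, roi_diameter_mm)
  })
  names(out) <- axes
  out
}
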