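#' Ice-water phantom scene
#'
#' A cylindrical 0-degree-C water compartment centred at the isocentre.
#' Thermal equilibrium fixes the true diffusion coefficient at the
#' literature reference for 0 degC water, `DC_True = 1.1e-3` mm^2/s, which is
#' what makes the phantom an absolute accuracy standard. The default
#' cylinder is wide enough that shifted-ROI series out to 8 cm stay inside
#' water, as required by the spatial-bias profiling experiment.
#'
#' @param grid a [grid_spec()]; default 120 x 120 x 3 voxels at
#'   2 x 2 x 4 mm (axial slices), isocentred.
#' @param diameter_mm water cylinder diameter (default 220).
#' @param adc true diffusion coefficient (default `1.1e-3` mm^2/s).
#' @param s0 water signal at b = 0 (default 1000).
#' @return A [phantom_scene()].
#' @export
icewater_scene <- function(grid = grid_spec(c(120L, 120L, 3L), c(2, 2, 4)),
                           diameter_mm = 220, adc = 1.1e-3, s0 = 1000) {
  length_mm <- grid$shape[3] * grid$spacing[3] + 2 * grid$spacing[3]
  phantom_scene(
    list(scene_cylinder(c(0, 0, 0), diameter_mm, length_mm,
                        adc = adc, s0 = s0, id = "water")),
    grid = grid, background_s0 = 0, background_adc = 0)
}

#' Reference diffusion coefficient of 0 degC water
#'
#' @return `1.1e-3` mm^2/s.
#' @export
dc_true_icewater <- function() 1.1e-3

#' Sphere-phantom layout
#'
#' Six water-filled spheres of diameters 10, 13, 17, 22, 28 and 37 mm,
#' centres equally spaced on a circle around the isocentre in the central
#' axial plane. The largest (37 mm) sphere is the reference for all
#' relative-error analyses.
#'
#' @param diameters_mm sphere diameters (default the six standard sizes).
#' @param ring_radius_mm radius of the circle of sphere centres (default 57).
#' @return Object of class `sphere_layout`: data frame with columns `id`,
#'   `cx`, `cy`, `cz`, `diameter_mm` plus attribute `reference_id`.
#' @export
sphere_layout <- function(diameters_mm = c(10, 13, 17, 22, 28, 37),
                          ring_radius_mm = 57) {
  diameters_mm <- as.numeric(diameters_mm)
  if (any(diameters_mm <= 0)) stop("sphere diameters must be positive")
  if (anyDuplicated(diameters_mm)) stop("sphere diameters must be unique")
  n <- length(diameters_mm)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  out <- data.frame(
    id = sprintf("sphere%02.0f", diameters_mm),
    cx = ring_radius_mm * cos(theta),
    cy = ring_radius_mm * sin(theta),
    cz = 0,
    diameter_mm = diameters_mm,
    stringsAsFactors = FALSE)
  attr(out, "reference_id") <- out$id[which.max(out$diameter_mm)]
  class(out) <- c("sphere_layout", "data.frame")
  out
}

#' Sphere-phantom scene
#'
#' Renders a [sphere_layout()] as room-temperature water spheres in a
#' low-signal solid background (default S0 at 10% of water and ADC
#' 0.3e-3 mm^2/s), so that partial-volume contamination at sphere edges has
#' a visible effect on measured ADC, as in the physical phantom insert.
#'
#' @param layout a [sphere_layout()].
#' @param grid a [grid_spec()]; default 80 x 80 x 12 voxels at
#'   2.5 x 2.5 x 5 mm (clinical-protocol voxels), isocentred.
#' @param sphere_adc true water ADC at room temperature
#'   (default `2.0e-3` mm^2/s).
#' @param sphere_s0 water signal at b = 0 (default 1000).
#' @param background_s0,background_adc insert material parameters.
#' @return A [phantom_scene()].
#' @export
sphere_phantom_scene <- function(layout = sphere_layout(),
                                 grid = grid_spec(c(80L, 80L, 12L),
                                                  c(2.5, 2.5, 5)),
                                 sphere_adc = 2.0e-3, sphere_s0 = 1000,
                                 background_s0 = 100,
                                 background_adc = 0.3e-3) {
  prims <- lapply(seq_len(nrow(layout)), function(i) {
    scene_sphere(c(layout$cx[i], layout$cy[i], layout$cz[i]),
                 layout$diameter_mm[i], adc = sphere_adc, s0 = sphere_s0,
                 id = layout$id[i])
  })
  phantom_scene(prims, grid = grid,
                background_s0 = background_s0,
                background_adc = background_adc)
}
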