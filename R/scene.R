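#' Phantom scene primitives
#'
#' A phantom scene is a set of non-overlapping geometric compartments
#' (spheres or z-axis cylinders), each with a proton-density scale `s0` and a
#' true diffusion coefficient `adc` (mm^2/s), embedded in a uniform
#' background compartment on a voxel grid.
#'
#' @param center numeric length 3, world mm.
#' @param diameter_mm primitive diameter (mm), > 0.
#' @param adc true diffusion coefficient (mm^2/s), >= 0.
#' @param s0 signal at b = 0 (arbitrary units), >= 0.
#' @param id optional label.
#' @name scene-primitives
NULL

#' @rdname scene-primitives
#' @export
scene_sphere <- function(center, diameter_mm, adc, s0, id = NULL) {
  new_primitive("sphere", center, diameter_mm, adc, s0, id, length_mm = NULL)
}

#' @rdname scene-primitives
#' @param length_mm cylinder length along z (mm).
#' @export
scene_cylinder <- function(center, diameter_mm, length_mm, adc, s0, id = NULL) {
  new_primitive("cylinder", center, diameter_mm, adc, s0, id,
                length_mm = length_mm)
}

new_primitive <- function(kind, center, diameter_mm, adc, s0, id, length_mm) {
  center <- as.numeric(center)
  stopifnot(length(center) == 3L)
  if (diameter_mm <= 0) stop("primitive diameter must be positive")
  if (adc < 0) stop("true ADC must be >= 0")
  if (s0 < 0) stop("S0 must be >= 0")
  if (identical(kind, "cylinder") && (is.null(length_mm) || length_mm <= 0))
    stop("cylinder length must be positive")
  structure(list(kind = kind, center = center, diameter_mm = diameter_mm,
                 length_mm = length_mm, adc = adc, s0 = s0,
                 id = if (is.null(id)) kind else as.character(id)),
            class = "scene_primitive")
}

#' Assemble a phantom scene
#'
#' @param primitives list of [scene_sphere()] / [scene_cylinder()] objects
#'   (may be empty).
#' @param grid a [grid_spec()].
#' @param background_s0,background_adc background compartment parameters.
#' @return Object of class `phantom_scene`.
#' @export
phantom_scene <- function(primitives, grid,
                          background_s0 = 0, background_adc = 0) {
  stopifnot(inherits(grid, "grid_spec"))
  if (inherits(primitives, "scene_primitive")) primitives <- list(primitives)
  for (p in primitives) stopifnot(inherits(p, "scene_primitive"))
  check_no_overlap(primitives)
  structure(list(primitives = primitives, grid = grid,
                 background_s0 = background_s0,
                 background_adc = background_adc),
            class = "phantom_scene")
}

# Conservative pairwise overlap test: exact for sphere-sphere; cylinders are
# checked via in-plane circle distance plus z-extent overlap.
check_no_overlap <- function(primitives) {
  n <- length(primitives)
  if (n < 2L) return(invisible(TRUE))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- primitives[[i]]; b <- primitives[[j]]
    if (primitives_overlap(a, b))
      stop(sprintf("scene primitives '%s' and '%s' overlap", a$id, b$id))
  }
  invisible(TRUE)
}

primitives_overlap <- function(a, b) {
  ra <- a$diameter_mm / 2; rb <- b$diameter_mm / 2
  if (a$kind == "sphere" && b$kind == "sphere") {
    return(sqrt(sum((a$center - b$center)^2)) < ra + rb)
  }
  # at least one cylinder: compare in-plane distance and z extents
  dxy <- sqrt(sum((a$center[1:2] - b$center[1:2])^2))
  za <- if (a$kind == "cylinder") a$length_mm / 2 else ra
  zb <- if (b$kind == "cylinder") b$length_mm / 2 else rb
  dxy < ra + rb && abs(a$center[3] - b$center[3]) < za + zb
}

point_inside <- function(prim, x, y, z) {
  r <- prim$diameter_mm / 2
  if (prim$kind == "sphere") {
    (x - prim$center[1])^2 + (y - prim$center[2])^2 +
      (z - prim$center[3])^2 < r^2
  } else {
    ((x - prim$center[1])^2 + (y - prim$center[2])^2 < r^2) &
      (abs(z - prim$center[3]) < prim$length_mm / 2)
  }
}

primitive_bbox <- function(prim) {
  r <- prim$diameter_mm / 2
  hz <- if (prim$kind == "cylinder") prim$length_mm / 2 else r
  rbind(lo = prim$center - c(r, r, hz), hi = prim$center + c(r, r, hz))
}

#' Rasterise a phantom scene to per-voxel compartment fractions
#'
#' Computes, for every voxel, the volume fraction occupied by each scene
#' compartment by counting `supersample^3` sub-voxel centres inside each
#' primitive. The fractions (not pre-mixed signals) are stored so that
#' partial-volume mixing can later happen in the signal domain, which is
#' what the scanner's voxel integration does and what produces the
#' characteristic small-target ADC errors.
#'
#' @param scene a [phantom_scene()].
#' @param supersample integer >= 1, sub-voxel sampling per axis (default 5).
#' @return Object of class `scene_raster`: list with `fractions` (4-D array,
#'   last dimension = compartments, background last), `s0` and `adc`
#'   per-compartment vectors, `grid`, and convenience `s0_map` / `adc_map`
#'   arrays holding the volume-weighted per-voxel averages.
#' @export
rasterize_scene <- function(scene, supersample = 5L) {
  stopifnot(inherits(scene, "phantom_scene"))
  supersample <- as.integer(supersample)
  if (supersample < 1L) stop("supersample must be >= 1")
  g <- scene$grid
  nprim <- length(scene$primitives)
  ncomp <- nprim + 1L
  frac <- array(0, dim = c(g$shape, ncomp))
  ax <- grid_axes(g)
  # sub-voxel centre offsets within one voxel, per axis
  sub_off <- lapply(1:3, function(k) {
    s <- g$spacing[k]
    ((seq_len(supersample) - 0.5) / supersample - 0.5) * s
  })
  for (p in seq_len(nprim)) {
    prim <- scene$primitives[[p]]
    bb <- primitive_bbox(prim)
    idx <- lapply(1:3, function(k) {
      which(ax[[k]] + g$spacing[k] / 2 > bb["lo", k] &
            ax[[k]] - g$spacing[k] / 2 < bb["hi", k])
    })
    if (any(lengths(idx) == 0L)) next
    # sub-voxel coordinates along each axis within the bbox
    cs <- lapply(1:3, function(k) {
      as.vector(outer(sub_off[[k]], ax[[k]][idx[[k]]], `+`))
    })
    nx <- length(idx[[1]]); ny <- length(idx[[2]]); nz <- length(idx[[3]])
    s <- supersample
    inside <- point_inside(
      prim,
      rep(cs[[1]], times = s * ny * s * nz),
      rep(rep(cs[[2]], each = s * nx), times = s * nz),
      rep(cs[[3]], each = s * nx * s * ny))
    dim(inside) <- c(s, nx, s, ny, s, nz)
    f <- apply(inside, c(2, 4, 6), mean)
    frac[idx[[1]], idx[[2]], idx[[3]], p] <-
      frac[idx[[1]], idx[[2]], idx[[3]], p] + f
  }
  fr2 <- frac
  dim(fr2) <- c(prod(g$shape), ncomp)  # flat view, safe for singleton axes
  tot <- if (nprim > 0L) rowSums(fr2[, seq_len(nprim), drop = FALSE])
         else numeric(prod(g$shape))
  if (any(tot > 1 + 1e-9))
    stop("overlapping primitives detected during rasterisation")
  fr2[, ncomp] <- 1 - tot
  frac <- array(fr2, dim = c(g$shape, ncomp))
  s0 <- c(vapply(scene$primitives, `[[`, numeric(1), "s0"), scene$background_s0)
  adc <- c(vapply(scene$primitives, `[[`, numeric(1), "adc"),
           scene$background_adc)
  s0_map <- array(as.vector(fr2 %*% s0), dim = g$shape)
  adc_map <- array(as.vector(fr2 %*% adc), dim = g$shape)
  structure(list(fractions = frac, s0 = s0, adc = adc, grid = g,
                 s0_map = s0_map, adc_map = adc_map,
                 compartments = c(vapply(scene$primitives, `[[`,
                                         character(1), "id"), "background")),
            class = "scene_raster")
}
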