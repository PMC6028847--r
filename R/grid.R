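#' Voxel grid geometry
#'
#' Defines a regular voxel grid in scanner (world) coordinates. World
#' coordinates are in mm with the magnet isocentre at (0, 0, 0); axes follow
#' the scanner convention x = right-left, y = up-down (positive towards the
#' table/bottom), z = slice direction. Voxel centres sit at
#' `origin + (index - 1 + 0.5) * spacing` per axis (1-based indices).
#'
#' @param shape integer vector of length 3: voxels along x, y, z.
#' @param spacing numeric length 3: voxel size in mm along x, y, z.
#' @param origin numeric length 3: world coordinate (mm) of the grid's
#'   low corner. Defaults to `-shape * spacing / 2`, which places the grid
#'   centre at the isocentre.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(c(120, 120, 3), c(2, 2, 4))
#' voxel_centers(g, "x")[1:3]
#' @export
grid_spec <- function(shape, spacing, origin = NULL) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  stopifnot(length(shape) == 3L, length(spacing) == 3L)
  if (any(shape < 1L)) stop("grid shape components must be >= 1")
  if (any(spacing <= 0)) stop("grid spacing must be positive")
  if (is.null(origin)) origin <- -shape * spacing / 2
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L)
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Voxel-centre world coordinates along one axis
#'
#' @param grid a [grid_spec()].
#' @param axis `"x"`, `"y"` or `"z"` (or 1:3).
#' @return Numeric vector of world coordinates (mm) of voxel centres.
#' @export
voxel_centers <- function(grid, axis) {
  ax <- axis_index(axis)
  grid$origin[ax] + (seq_len(grid$shape[ax]) - 0.5) * grid$spacing[ax]
}

axis_index <- function(axis) {
  if (is.character(axis)) {
    ax <- match(tolower(axis), c("x", "y", "z"))
    if (is.na(ax)) stop("axis must be one of 'x', 'y', 'z'")
    return(ax)
  }
  ax <- as.integer(axis)
  if (ax < 1L || ax > 3L) stop("axis index must be 1, 2 or 3")
  ax
}

#' Full voxel-centre coordinate arrays
#'
#' @param grid a [grid_spec()].
#' @return A list with components `x`, `y`, `z`, each a numeric vector of
#'   per-axis voxel-centre coordinates (mm).
#' @keywords internal
grid_axes <- function(grid) {
  list(x = voxel_centers(grid, 1L),
       y = voxel_centers(grid, 2L),
       z = voxel_centers(grid, 3L))
}

grids_equal <- function(a, b, tol = 1e-9) {
  identical(a$shape, b$shape) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}
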