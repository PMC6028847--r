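# Shared fixtures and independent brute-force oracles.

small_grid <- function(shape = c(20L, 20L, 3L), spacing = c(2, 2, 4)) {
  grid_spec(shape, spacing)
}

# Brute-force sub-voxel inside-fraction of a sphere, independent of the
# rasteriser: explicit triple loop over sub-voxel centres.
brute_sphere_fraction <- function(grid, center, diameter, ivox, supersample) {
  sp <- grid$spacing
  ctr <- c(voxel_centers(grid, 1)[ivox[1]],
           voxel_centers(grid, 2)[ivox[2]],
           voxel_centers(grid, 3)[ivox[3]])
  r2 <- (diameter / 2)^2
  inside <- 0L
  for (a in seq_len(supersample)) for (b in seq_len(supersample))
    for (cc in seq_len(supersample)) {
      p <- ctr + (c(a, b, cc) - 0.5) / supersample * sp - sp / 2
      if (sum((p - center)^2) < r2) inside <- inside + 1L
    }
  inside / supersample^3
}

# Brute-force lattice count of voxel centres strictly inside a circle.
brute_circle_count <- function(spacing, diameter, center_offset = c(0, 0)) {
  r2 <- (diameter / 2)^2
  cnt <- 0L
  rng <- ceiling(diameter / min(spacing)) + 2L
  for (i in -rng:rng) for (j in -rng:rng) {
    x <- i * spacing[1] - center_offset[1]
    y <- j * spacing[2] - center_offset[2]
    if (x^2 + y^2 < r2) cnt <- cnt + 1L
  }
  cnt
}

# Exact Wilcoxon signed-rank p by full 2^n sign-pattern enumeration.
enumerate_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  Ws <- apply(signs, 1, function(s) sum(r[s]))
  p_le <- mean(Ws <= W + 1e-9)
  p_ge <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Textbook Pearson correlation, written independently of stats::cor.
brute_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# A uniform one-compartment raster for quick DWI synthesis.
uniform_raster <- function(grid = small_grid(), adc = 1.1e-3, s0 = 1000) {
  scene <- phantom_scene(list(), grid, background_s0 = s0,
                         background_adc = adc)
  rasterize_scene(scene, supersample = 1L)
}
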