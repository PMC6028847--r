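const_map <- function(grid, value = 2e-3, mask = NULL) {
  vals <- array(value, dim = grid$shape)
  if (is.null(mask)) mask <- array(TRUE, dim = grid$shape)
  adc_map(vals, mask, c(0, 800), grid)
}

test_that("circle selection matches brute-force lattice enumeration", {
  g <- grid_spec(c(41L, 41L, 1L), c(2, 2, 4))
  # 25-mm circle on a 2-mm grid centred on a voxel centre: i^2+j^2 < 39.0625
  vox <- select_voxels(g, roi_circle(c(0, 0, 0), 25))
  expect_equal(attr(vox, "n"), 121L)
  expect_equal(attr(vox, "n"), brute_circle_count(c(2, 2), 25))
  # other diameters and off-centre placements agree with the oracle
  for (d in c(10, 16.5, 22)) {
    for (off in list(c(0, 0), c(1, 0.5))) {
      vox <- select_voxels(g, roi_circle(c(off[1], off[2], 0), d))
      expect_equal(attr(vox, "n"), brute_circle_count(c(2, 2), d, off))
    }
  }
})

test_that("tiny circles select a single voxel; off-grid ROIs error", {
  g <- grid_spec(c(11L, 11L, 1L), c(2, 2, 4))
  vox <- select_voxels(g, roi_circle(c(0, 0, 0), 1.5))
  expect_equal(attr(vox, "n"), 1L)
  expect_error(select_voxels(g, roi_sphere(c(500, 0, 0), 10)), "empty ROI")
})

test_that("selection is translation-consistent by one voxel pitch", {
  g <- grid_spec(c(31L, 31L, 1L), c(2, 2, 4))
  v0 <- select_voxels(g, roi_circle(c(0, 0, 0), 13))
  v1 <- select_voxels(g, roi_circle(c(2, 0, 0), 13))
  expect_equal(sort(as.integer(v1)), sort(as.integer(v0) + 1L))
})

test_that("ROI statistics: hand values, constant maps and masking", {
  g <- grid_spec(c(3L, 1L, 1L), c(2, 2, 2))
  vals <- array(c(1, 2, 3) * 1e-3, dim = c(3, 1, 1))
  m <- adc_map(vals, array(TRUE, c(3, 1, 1)), c(0, 800), g)
  st <- roi_statistics(m, 1:3)
  expect_equal(st$n, 3L)
  expect_equal(st$mean, 2e-3)
  expect_equal(st$sd, 1e-3)
  # constant map: sd exactly 0
  stc <- roi_statistics(const_map(g, 5e-4), 1:3)
  expect_equal(stc$sd, 0)
  # masking halves n and restricts the mean to valid voxels
  m2 <- adc_map(vals, array(c(TRUE, FALSE, TRUE), c(3, 1, 1)), c(0, 800), g)
  st2 <- roi_statistics(m2, 1:3)
  expect_equal(st2$n, 2L)
  expect_equal(st2$mean, 2e-3)
  m3 <- adc_map(vals, array(FALSE, c(3, 1, 1)), c(0, 800), g)
  expect_error(roi_statistics(m3, 1:3), "empty ROI")
})

test_that("statistics are invariant under voxel enumeration order", {
  g <- grid_spec(c(5L, 5L, 1L), c(2, 2, 2))
  set.seed(2)
  vals <- array(runif(25, 1e-3, 2e-3), dim = c(5, 5, 1))
  m <- adc_map(vals, array(TRUE, c(5, 5, 1)), c(0, 800), g)
  vox <- select_voxels(g, roi_circle(c(0, 0, 0), 8))
  a <- roi_statistics(m, vox)
  b <- roi_statistics(m, rev(vox))
  expect_equal(a$mean, b$mean)
  expect_equal(a$sd, b$sd)
})

test_that("shifted series: constant map gives all-zero relative values", {
  g <- grid_spec(c(61L, 61L, 1L), c(2, 2, 4))
  prof <- shifted_roi_series(const_map(g), "y", 20, 2, 10)
  expect_equal(prof$rel_pct, c(0, 0, 0))
  expect_equal(prof$distance_cm, c(0, 2, 4))
})

test_that("shifted series truncates with a warning when ROIs leave the grid", {
  g <- grid_spec(c(21L, 21L, 1L), c(2, 2, 4))
  expect_warning(prof <- shifted_roi_series(const_map(g), "x", 20, 4, 10),
                 "truncated")
  expect_lt(nrow(prof), 5)
})

test_that("replaying the measured vertical profile returns the printed values", {
  # piecewise-constant map along y: each shifted ROI sits inside one step
  printed <- c(0.0, -0.9, 9.3, 13.0, 24.1)
  g <- grid_spec(c(5L, 95L, 1L), c(2, 2, 4))
  ref <- 1.1e-3
  yc <- voxel_centers(g, 2)
  vals <- array(0, dim = g$shape)
  for (i in seq_len(g$shape[2])) {
    band <- pmin(pmax(round(yc[i] / 20), 0), 4)  # nearest 2-cm station
    vals[, i, ] <- ref * (1 + printed[band + 1] / 100)
  }
  m <- adc_map(vals, array(TRUE, g$shape), c(0, 800), g)
  prof <- shifted_roi_series(m, "y", 20, 4, 6)
  expect_equal(prof$rel_pct, printed, tolerance = 1e-12)
})

test_that("nested ROIs on a constant map have equal means and zero sd", {
  g <- grid_spec(c(21L, 21L, 9L), c(2, 2, 2))
  m <- const_map(g, 1.7e-3)
  a <- roi_statistics(m, select_voxels(g, roi_sphere(c(0, 0, 0), 10)))
  b <- roi_statistics(m, select_voxels(g, roi_sphere(c(0, 0, 0), 16)))
  expect_equal(a$mean, b$mean)
  expect_equal(a$sd, 0)
  expect_equal(b$sd, 0)
  expect_lt(a$n, b$n)
})
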