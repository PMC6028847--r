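test_that("grid invariants: voxel centres at half-integer offsets, isocentre default", {
  g <- grid_spec(c(10L, 10L, 4L), c(2, 2, 4))
  expect_equal(voxel_centers(g, "x")[1], g$origin[1] + 1)
  expect_equal(mean(range(voxel_centers(g, "y"))), 0)
  expect_error(grid_spec(c(10, 10, 1), c(0, 2, 2)), "spacing")
  expect_error(grid_spec(c(0, 10, 1), c(2, 2, 2)), "shape")
})

test_that("rasterisation matches a brute-force sub-voxel oracle", {
  g <- grid_spec(c(10L, 10L, 5L), c(2, 2, 5))
  sph <- scene_sphere(c(0, 0, 0), 10, adc = 2e-3, s0 = 1000)
  sc <- phantom_scene(list(sph), g, background_s0 = 100,
                      background_adc = 3e-4)
  ra <- rasterize_scene(sc, supersample = 5L)
  # compare a 3x3x3 block of voxels around the centre against the oracle
  for (i in 4:6) for (j in 4:6) for (k in 2:4) {
    expect_equal(ra$fractions[i, j, k, 1],
                 brute_sphere_fraction(g, c(0, 0, 0), 10, c(i, j, k), 5L),
                 tolerance = 1e-12)
  }
  # fractions sum to one everywhere
  expect_equal(max(abs(apply(ra$fractions, 1:3, sum) - 1)), 0,
               tolerance = 1e-12)
})

test_that("aligned geometry and empty scenes rasterise trivially", {
  g <- grid_spec(c(5L, 5L, 5L), c(2, 2, 2))
  # sphere circumscribing exactly one voxel centre: strict inside test at
  # supersample 1 marks that voxel fully inside, neighbours outside
  sph <- scene_sphere(c(0, 0, 0), 2, adc = 1e-3, s0 = 1)
  ra <- rasterize_scene(phantom_scene(list(sph), g), supersample = 1L)
  expect_equal(ra$fractions[3, 3, 3, 1], 1)
  expect_equal(sum(ra$fractions[, , , 1]), 1)
  # empty scene: background everywhere
  ra0 <- rasterize_scene(phantom_scene(list(), g, background_s0 = 7,
                                       background_adc = 5e-4))
  expect_true(all(ra0$s0_map == 7))
  expect_true(all(ra0$adc_map == 5e-4))
})

test_that("overlapping primitives are rejected", {
  g <- small_grid()
  a <- scene_sphere(c(0, 0, 0), 10, 1e-3, 1)
  b <- scene_sphere(c(4, 0, 0), 10, 1e-3, 1)
  expect_error(phantom_scene(list(a, b), g), "overlap")
})

test_that("DWI synthesis follows the mono-exponential closed form", {
  ra <- uniform_raster(adc = 1.1e-3, s0 = 1000)
  ser <- synthesize_dwi(ra, c(0, 800))[[1]]
  expect_equal(ser$signal[1, 1, 1, 2], 1000 * exp(-0.88), tolerance = 1e-12)
  # b = 0 reproduces S0 exactly
  expect_equal(max(abs(ser$signal[, , , 1] - 1000)), 0)
  expect_error(synthesize_dwi(ra, c(-10, 800)), "non-negative")
})

test_that("same seed gives bit-identical series; different seeds differ", {
  ra <- uniform_raster()
  s1 <- synthesize_dwi(ra, c(0, 800), noise_sd = 10, n_repeats = 2, seed = 42)
  s2 <- synthesize_dwi(ra, c(0, 800), noise_sd = 10, n_repeats = 2, seed = 42)
  s3 <- synthesize_dwi(ra, c(0, 800), noise_sd = 10, n_repeats = 2, seed = 43)
  expect_identical(s1[[1]]$signal, s2[[1]]$signal)
  expect_identical(s1[[2]]$signal, s2[[2]]$signal)
  expect_false(identical(s1[[1]]$signal, s3[[1]]$signal))
  # repeats differ only by noise realisation
  expect_false(identical(s1[[1]]$signal, s1[[2]]$signal))
})

test_that("Rician noise: identity at sigma 0, Rayleigh mean at v = 0, unbiased at high SNR", {
  v <- matrix(runif(100), 10)
  expect_identical(add_rician_noise(v, 0), v)
  set.seed(7)
  n <- 2e5
  zero_mean <- mean(add_rician_noise(rep(0, n), 1))
  # Rayleigh mean sqrt(pi/2) ~ 1.2533; MC SE ~ sqrt((2 - pi/2)/n)
  se <- sqrt((2 - pi / 2) / n)
  expect_lt(abs(zero_mean - sqrt(pi / 2)), 4 * se)
  hi <- add_rician_noise(rep(100, n), 1)
  expect_gte(mean(hi) / 100, 1.0)
  expect_lte(mean(hi) / 100, 1.0001)
})

test_that("bias field: zero at isocentre, exact quadratic fit, zero-profile fit", {
  expect_equal(eval_bias(default_bias_field(), cbind(0, 0, 0)), 0)
  bf <- fit_bias_field(list(y = data.frame(d = c(0, 2, 4),
                                           v = c(0, 4, 16))), degree = 2)
  expect_equal(bf$coef$y, c(0, 0.01), tolerance = 1e-12)
  expect_equal(eval_bias(bf, cbind(0, 30, 0)), 0.01 * 9, tolerance = 1e-12)
  flat <- fit_bias_field(list(x = data.frame(d = c(0, 2, 4, 6),
                                             v = c(0, 0, 0, 0))))
  expect_equal(eval_bias(flat, cbind(55, -12, 8)), 0, tolerance = 1e-12)
  expect_error(fit_bias_field(list(y = data.frame(d = c(0, 2), v = c(0, 1)))),
               "3 profile points")
  expect_error(fit_bias_field(list(y = data.frame(d = c(1, 2, 3),
                                                  v = c(1, 2, 3)))),
               "isocentre")
})

test_that("default bias field reproduces the fitted vertical trend and no horizontal trend", {
  bf <- default_bias_field()
  expect_length(bf$coef$x, 0)
  # fitted field passes near the measured vertical profile
  prof <- spatial_shift_profiles()$y
  fitted <- 100 * eval_bias(bf, cbind(0, prof$distance_cm * 10, 0))
  expect_lt(max(abs(fitted - prof$rel_error_pct)), 3)
})

test_that("reader study: determinism, trivial zero-noise case, contamination sign", {
  cfg0 <- reader_study_config(contamination = c(0, 0), volume_scale = c(1, 1),
                              noise_sd = 0)
  t1 <- simulate_reader_study(cfg0, seed = 5)
  t2 <- simulate_reader_study(cfg0, seed = 5)
  expect_identical(t1, t2)
  # zero contamination + zero noise: all four measurements of a node equal
  spread <- tapply(t1$mean_adc, interaction(t1$subject, t1$node, drop = TRUE),
                   function(v) diff(range(v)))
  expect_equal(max(spread), 0)
  ba <- bland_altman(paired_differences(t1, "readers", "relative"))
  expect_equal(ba$bias, 0)
  # reader-2 contamination by brighter surround: reader-2 means larger
  cfg2 <- reader_study_config(n_nodes_total = 60L, nodes_per_subject = 5L,
                              contamination = c(0, 0.1), noise_sd = 0)
  tt <- simulate_reader_study(cfg2, seed = 9)
  m1 <- mean(tt$mean_adc[tt$reader == 1])
  m2 <- mean(tt$mean_adc[tt$reader == 2])
  expect_gt(m2, m1)
})

test_that("reader study recovers the configured node-ADC distribution", {
  cfg <- reader_study_config(n_subjects = 13L, nodes_per_subject = 4L)
  tab <- simulate_reader_study(cfg, seed = 21)
  true_adc <- attr(tab, "true_adc")
  se <- cfg$node_adc_sd / sqrt(length(true_adc))
  expect_lt(abs(mean(true_adc) - cfg$node_adc_mean), 3 * se)
  expect_error(reader_study_config(contamination = c(0, 1)), "contamination")
  expect_error(reader_study_config(nodes_per_subject = 2), "four nodes")
})
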