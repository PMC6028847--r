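stats_list <- function(means, sds = 0, n = 10L) {
  sds <- rep_len(sds, length(means))
  lapply(seq_along(means), function(i)
    dwiqc:::roi_stats(n, means[i], sds[i]))
}

test_that("repeatability CV: hand value, zero case, scale invariance", {
  rs <- repeat_series(stats_list(c(1.0, 1.1) * 1e-3))
  expect_equal(cv_repeatability(rs), 100 * sd(c(1.0, 1.1)) / 1.05,
               tolerance = 1e-12)
  expect_equal(round(cv_repeatability(rs), 3), 6.734)
  expect_equal(cv_repeatability(repeat_series(stats_list(rep(2e-3, 4)))), 0)
  rs_scaled <- repeat_series(stats_list(c(1.0, 1.1) * 7e-3))
  expect_equal(cv_repeatability(rs_scaled), cv_repeatability(rs),
               tolerance = 1e-12)
  expect_error(cv_repeatability(repeat_series(stats_list(1e-3))), ">= 2")
})

test_that("repeatability coefficient is literally 2.77 sigma_R", {
  means <- c(2.0, 2.1, 1.9, 2.0) * 1e-3
  rs <- repeat_series(stats_list(means))
  expect_equal(repeatability_coefficient(rs), 2.77 * sd(means),
               tolerance = 1e-15)
  expect_equal(repeatability_coefficient(rs) / rs$sigma_R, 2.77)
  expect_equal(repeatability_coefficient(
    repeat_series(stats_list(c(1, 1) * 1e-3))), 0)
})

test_that("bias estimate: both forms, sign preserved", {
  b <- adc_bias_estimate(1.2e-3, 1.1e-3)
  expect_equal(b$absolute, 1.0e-4, tolerance = 1e-12)
  expect_equal(b$percent, 100 / 11, tolerance = 1e-12)
  expect_equal(adc_bias_estimate(1.1e-3, 1.1e-3)$percent, 0)
  expect_equal(adc_bias_estimate(1.0e-3, 1.1e-3)$percent, -100 / 11,
               tolerance = 1e-12)
})

test_that("noise estimate is the within-ROI spatial CV", {
  st <- dwiqc:::roi_stats(50L, 1.0e-3, 0.09e-3)
  expect_equal(adc_noise_estimate(st), 9.0, tolerance = 1e-12)
  expect_equal(adc_noise_estimate(dwiqc:::roi_stats(10L, 1e-3, 0)), 0)
})

test_that("b-value dependence uses the first argument as denominator", {
  expect_equal(b_value_dependence(1.000e-3, 1.007e-3), 0.7, tolerance = 1e-12)
  expect_equal(b_value_dependence(1.007e-3, 1.000e-3), 100 * 7 / 1007,
               tolerance = 1e-12)
  expect_equal(b_value_dependence(2e-3, 2e-3), 0)
})

test_that("SNR_nDyn: temporal statistics, undefined case, scale invariance", {
  dims <- c(30L, 30L, 1L)
  vox <- 1:900
  same <- replicate(4, array(100, dims), simplify = FALSE)
  expect_error(snr_ndyn(same, vox), "undefined SNR")
  # Gaussian noise: mean temporal SD underestimates sigma by c4(n)
  n_rep <- 4L
  c4 <- sqrt(2 / (n_rep - 1)) * gamma(n_rep / 2) / gamma((n_rep - 1) / 2)
  expected <- 100 / (2 * c4)
  set.seed(31)
  ratios <- replicate(5, {
    reps <- replicate(n_rep, array(100 + rnorm(900, 0, 2), dims),
                      simplify = FALSE)
    snr_ndyn(reps, vox)
  })
  expect_lt(abs(mean(ratios) / expected - 1), 0.05)
  # joint rescaling of signal and noise leaves SNR unchanged
  set.seed(8)
  reps <- replicate(n_rep, array(100 + rnorm(900, 0, 2), dims),
                    simplify = FALSE)
  doubled <- lapply(reps, function(a) 2 * a)
  expect_equal(snr_ndyn(doubled, vox), snr_ndyn(reps, vox), tolerance = 1e-12)
})

test_that("Pearson matches a brute-force oracle and flags degenerate input", {
  expect_equal(pearson_correlation(1:5, 2 * (1:5) + 1)$r, 1)
  set.seed(12)
  for (k in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    expect_equal(pearson_correlation(x, y)$r, brute_pearson(x, y),
                 tolerance = 1e-12)
  }
  expect_error(pearson_correlation(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})

test_that("Pearson on the measured shift profiles gives the reported correlations", {
  pr <- spatial_shift_profiles()
  r_h <- pearson_correlation(pr$x$distance_cm, pr$x$rel_error_pct)$r
  r_v <- pearson_correlation(pr$y$distance_cm, pr$y$rel_error_pct)$r
  expect_equal(round(r_h, 2), 0.25)
  expect_equal(round(r_v, 2), 0.95)
})

test_that("QC report flags claims with strict inequalities", {
  thr <- qiba_thresholds()
  # a perfect noiseless phantom: zero metrics, all claims pass, SNR flagged
  ex <- icewater_qc_experiment(seed = 1)
  r <- ex$report
  expect_true(all(abs(r$metrics$bias_pct) < 1e-9))
  expect_true(all(r$metrics$cv_pct == 0))
  expect_true(all(r$metrics$cv_pass, r$metrics$rc_pass, r$metrics$bias_pass,
                  r$metrics$noise_pass))
  expect_true(r$bdep_pass)
  expect_true(is.na(r$snr))
  expect_match(r$snr_note, "undefined")
  # boundary equality fails a strict '<' claim
  rs <- stats_list(c(1.0, 1.1) * 1e-3)
  rep_cv <- cv_repeatability(repeat_series(rs))
  thr_eq <- qiba_thresholds(cv_max = rep_cv)
  rpt <- qc_report(list(b800 = rs),
                   b0_repeats = replicate(2, array(runif(4), c(2, 2, 1)),
                                          simplify = FALSE),
                   voxels = 1:4, thresholds = thr_eq)
  expect_false(rpt$metrics$cv_pass)
})

test_that("a global ADC scale inflation fails only the bias claim", {
  sc <- icewater_scene(adc = 1.1e-3 * 1.04)  # +4% true-value offset
  ex <- icewater_qc_experiment(scene = sc, seed = 1)
  r <- ex$report
  expect_true(all(!r$metrics$bias_pass))
  expect_equal(r$metrics$bias_pct, rep(4, 3), tolerance = 1e-9)
  expect_true(all(r$metrics$cv_pass, r$metrics$rc_pass, r$metrics$noise_pass))
  expect_true(r$bdep_pass)
})
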