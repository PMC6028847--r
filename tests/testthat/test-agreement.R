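toy_table <- function(r1, r2) {
  n <- length(r1)
  data.frame(subject = rep(1, 2 * n), node = rep(seq_len(n), 2),
             reader = rep(1:2, each = n), session = 1,
             volume_cm3 = 1, mean_adc = c(r1, r2), sd_adc = 0.1e-3)
}

test_that("paired differences: fixed order, pair-mean denominator, antisymmetry", {
  tab <- toy_table(c(0.9e-3, 1.2e-3), c(1.0e-3, 1.2e-3))
  d_abs <- paired_differences(tab, "readers", "absolute")
  expect_equal(sort(d_abs), sort(c(-1e-4, 0)))
  d_rel <- paired_differences(tab, "readers", "relative")
  expect_equal(sort(d_rel)[1], 100 * (0.9 - 1.0) / 0.95, tolerance = 1e-12)
  # equal values give zero differences
  tab0 <- toy_table(c(1e-3, 1e-3), c(1e-3, 1e-3))
  expect_equal(paired_differences(tab0, "readers", "absolute"),
               c(0, 0), ignore_attr = TRUE)
  # swapping readers negates every difference
  tab_sw <- tab
  tab_sw$reader <- 3 - tab_sw$reader
  expect_equal(sort(paired_differences(tab_sw, "readers", "absolute")),
               sort(-d_abs), ignore_attr = TRUE)
})

test_that("incomplete pairs are dropped and counted", {
  tab <- toy_table(c(0.9e-3, 1.1e-3), c(1.0e-3, 1.2e-3))
  tab <- tab[-4, ]  # node 2 loses its reader-2 member
  d <- paired_differences(tab, "readers", "absolute")
  expect_equal(attr(d, "n_units"), 1L)
  expect_equal(attr(d, "n_dropped"), 1L)
  expect_error(paired_differences(tab[tab$reader == 1, ], "readers"),
               "no complete pairs")
})

test_that("Bland-Altman: hand values and degenerate constant differences", {
  res <- bland_altman(c(-2, 0, 2))
  expect_equal(res$bias, 0)
  expect_equal(res$sd_diff, 2)
  expect_equal(res$loa_low, -3.92)
  expect_equal(res$loa_high, 3.92)
  resc <- bland_altman(c(3, 3, 3))
  expect_equal(resc$loa_low, 3)
  expect_equal(resc$loa_high, 3)
  expect_error(bland_altman(1), ">= 2")
})

test_that("Bland-Altman antisymmetry under pair reversal", {
  set.seed(4)
  d <- rnorm(20)
  a <- bland_altman(d); b <- bland_altman(-d)
  expect_equal(b$bias, -a$bias)
  expect_equal(b$loa_low, -a$loa_high)
  expect_equal(b$loa_high, -a$loa_low)
})

test_that("Wilcoxon signed rank: exact examples and the zero-drop rule", {
  # all-positive differences, n = 6: maximal W, exact p = 2/64
  w <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6))
  expect_equal(w$statistic, 21)
  expect_equal(w$p_value, 2 / 64)
  # symmetric differences sit at the null centre
  ws <- wilcoxon_signed_rank(c(-1, 1, -2, 2, -3, 3))
  expect_equal(ws$p_value, 1)
  # adding a zero difference changes nothing
  wz <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6, 0))
  expect_equal(wz$statistic, w$statistic)
  expect_equal(wz$p_value, w$p_value)
  expect_equal(wz$n, 6L)
  expect_error(wilcoxon_signed_rank(c(0, 0, 0)), "degenerate")
})

test_that("exact Wilcoxon p matches full sign-pattern enumeration (with ties)", {
  set.seed(77)
  cases <- c(
    lapply(5:10, function(n) rnorm(n)),
    list(c(1, 1, 2, 2, 3, -3, 4),          # tied magnitudes
         c(-1, -1, -1, 2, 2, 3, 5, 5),
         round(rnorm(12), 1)))             # rounding-induced ties
  for (d in cases) {
    got <- suppressWarnings(wilcoxon_signed_rank(d))
    expect_equal(got$p_value, enumerate_wilcoxon_p(d), tolerance = 1e-12)
  }
})

test_that("exact Wilcoxon p matches stats::wilcox.test when ties are absent", {
  set.seed(5)
  for (k in 1:5) {
    d <- rnorm(10)
    got <- wilcoxon_signed_rank(d)
    ref <- wilcox.test(d, exact = TRUE)
    expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-12)
    expect_equal(got$statistic, unname(ref$statistic))
  }
})

test_that("large-n Wilcoxon uses a continuity-corrected normal approximation", {
  set.seed(6)
  d <- rnorm(40, 0.3)
  got <- wilcoxon_signed_rank(d)
  ref <- wilcox.test(d, exact = FALSE, correct = TRUE)
  expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-9)
  expect_match(got$method, "normal")
})

test_that("meaningful-change range is log-symmetric and reproduces the published range", {
  mc <- meaningful_change_range(-9.2, 10.4)
  expect_equal(round(mc$lower_pct), -13)
  expect_equal(round(mc$upper_pct), 15)
  expect_equal(log(1 + mc$upper_pct / 100) + log(1 + mc$lower_pct / 100), 0,
               tolerance = 1e-9)
  tiny <- meaningful_change_range(-1e-6, 1e-6)
  expect_equal(tiny$lower_pct, 0, tolerance = 1e-5)
  expect_equal(tiny$upper_pct, 0, tolerance = 1e-5)
  expect_error(meaningful_change_range(0, 0), "positive")
})

test_that("injected inter-reader bias is recovered across a grid of effects", {
  for (beta in c(-10, -5.5, 0, 5)) {
    f <- if (beta < 0) contamination_for_bias(beta) else 0
    surround_mean <- 1.8e-3
    if (beta > 0) {
      # positive bias needs a darker surround for reader 2
      surround_mean <- 0.4e-3
      f <- contamination_for_bias(beta, surround_adc_mean = surround_mean)
    }
    cfg <- reader_study_config(n_nodes_total = 54L,
                               surround_adc_mean = surround_mean,
                               contamination = c(0, f))
    biases <- sapply(1:3, function(s) {
      tab <- simulate_reader_study(cfg, seed = 100 + s)
      bland_altman(paired_differences(tab, "readers", "relative"))$bias
    })
    se <- sd(biases) / sqrt(length(biases)) + 1e-6
    expect_lt(abs(mean(biases) - beta), max(3 * se, 2.5))
  }
})

test_that("zero-noise reader simulation yields degenerate agreement", {
  cfg <- reader_study_config(contamination = c(0, 0), volume_scale = c(1, 1),
                             noise_sd = 0)
  tab <- simulate_reader_study(cfg, seed = 3)
  res <- agreement_analysis(tab, "readers", "absolute")
  expect_equal(res$bias, 0)
  expect_equal(res$loa_low, 0)
  expect_equal(res$loa_high, 0)
  expect_true(is.na(res$wilcoxon$p_value))
  expect_match(res$wilcoxon$method, "degenerate")
})
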