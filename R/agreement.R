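#' Paired differences from a reader-measurement table
#'
#' Builds the per-node differences entering a Bland-Altman analysis.
#' For `compare = "readers"` each node's per-reader value is first averaged
#' over sessions, and the difference is reader 1 minus reader 2
#' (inter-observer). For `compare = "sessions"` the table is restricted to
#' one reader and the difference is session 1 minus session 2
#' (intra-observer). Nodes missing either member of a pair are dropped with
#' a recorded count. The relative difference uses the pair mean as
#' denominator: `100 * (a - b) / ((a + b) / 2)`.
#'
#' @param table data.frame with columns `subject`, `node`, `reader`,
#'   `session` and a value column.
#' @param compare `"readers"` or `"sessions"`.
#' @param scale `"absolute"` (value units) or `"relative"` (%).
#' @param value column to compare (default `"mean_adc"`).
#' @param reader for `compare = "sessions"`: which reader (default 1).
#' @return Numeric vector of differences with attributes `n_units` and
#'   `n_dropped`.
#' @export
paired_differences <- function(table, compare = c("readers", "sessions"),
                               scale = c("absolute", "relative"),
                               value = "mean_adc", reader = 1L) {
  compare <- match.arg(compare)
  scale <- match.arg(scale)
  stopifnot(all(c("subject", "node", "reader", "session", value) %in%
                names(table)))
  if (compare == "sessions") table <- table[table$reader == reader, ]
  key <- interaction(table$subject, table$node, drop = TRUE)
  arm <- if (compare == "readers") table$reader else table$session
  a <- tapply(table[[value]][arm == 1], droplevels(key[arm == 1]), mean)
  b <- tapply(table[[value]][arm == 2], droplevels(key[arm == 2]), mean)
  common <- intersect(names(a), names(b))
  n_all <- length(unique(key))
  if (length(common) == 0L) stop("no complete pairs")
  a <- a[common]; b <- b[common]
  d <- if (scale == "absolute") a - b else 100 * (a - b) / ((a + b) / 2)
  structure(as.numeric(d), n_units = length(common),
            n_dropped = n_all - length(common))
}

#' Bland-Altman bias and limits of agreement
#'
#' `bias = mean(differences)`, `LoA = bias +/- 1.96 * sample SD`.
#'
#' @param differences numeric vector of paired differences (n >= 2), e.g.
#'   from [paired_differences()].
#' @param scale label recorded in the result (`"absolute"` or
#'   `"relative"`).
#' @return Object of class `agreement_result`: list(`scale`, `n`, `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `n_dropped`).
#' @export
bland_altman <- function(differences, scale = "absolute") {
  d <- as.numeric(differences)
  if (length(d) < 2L) stop("need >= 2 differences")
  bias <- mean(d)
  sdd <- stats::sd(d)
  structure(list(scale = scale, n = length(d), bias = bias, sd_diff = sdd,
                 loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
                 n_dropped = attr(differences, "n_dropped")),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> (%s) n = %d: bias %.4g, LoA [%.4g, %.4g]\n",
              x$scale, x$n, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Wilcoxon signed-rank test for paired values
#'
#' Two-sided signed-rank test on paired differences. Zero differences are
#' dropped; tied absolute differences receive mid-ranks. For n <= 25 the
#' exact null distribution of the positive-rank sum is computed by
#' generating-function convolution over the (doubled, hence integer)
#' mid-ranks — exact even in the presence of ties. For larger n a normal
#' approximation with continuity correction and the usual tie-corrected
#' variance is used.
#'
#' @param x paired differences, or the first member of each pair if `y`
#'   is given.
#' @param y optional second member; differences are `x - y`.
#' @param exact_max largest n for which the exact distribution is
#'   enumerated (default 25).
#' @return list(`statistic` = positive-rank sum W, `p_value`, `n`
#'   (non-zero pairs), `method`).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25L) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("degenerate test: all differences are zero")
  if (n < 5L) warning("fewer than 5 non-zero differences; p is unstable")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact: distribution of W over 2^n sign patterns via polynomial
    # convolution in the doubled ranks (mid-ranks are multiples of 1/2)
    r2 <- as.integer(round(2 * r))
    maxs <- sum(r2)
    poly <- numeric(maxs + 1L)  # poly[k+1] = #patterns with 2W == k
    poly[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), poly[seq_len(maxs + 1L - ri)])
      poly <- poly + shifted
    }
    probs <- poly / 2^n
    w2 <- as.integer(round(2 * W))
    p_le <- sum(probs[seq_len(w2 + 1L)])
    p_ge <- sum(probs[(w2 + 1L):(maxs + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact signed-rank (sign-pattern convolution)"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with continuity correction"
  }
  list(statistic = W, p_value = p, n = n, method = method)
}

#' Meaningful-change range from intra-observer limits of agreement
#'
#' Reconstructs an asymmetric range of relative ADC change outside which a
#' longitudinal change is unlikely to be measurement noise. The LoA
#' half-width `h` (%) — the mean of |LoA low| and |LoA high| — is scaled by
#' `sqrt(2)` (a change involves two measurements) and treated as a limit on
#' the log scale, giving the log-symmetric range
#' `[100 (e^-c - 1), 100 (e^c - 1)]` with `c = sqrt(2) h / 100`.
#'
#' @param loa_low_pct,loa_high_pct intra-observer relative LoA endpoints (%).
#' @return Object of class `meaningful_change_range`: list(`lower_pct`,
#'   `upper_pct`, `half_width_pct`, `method`).
#' @export
meaningful_change_range <- function(loa_low_pct, loa_high_pct) {
  h <- mean(abs(c(loa_low_pct, loa_high_pct)))
  if (h <= 0) stop("LoA half-width must be positive")
  cc <- sqrt(2) * h / 100
  structure(list(lower_pct = 100 * (exp(-cc) - 1),
                 upper_pct = 100 * (exp(cc) - 1),
                 half_width_pct = h,
                 method = paste("log-symmetric reconstruction from",
                                "sqrt(2)-scaled intra-observer LoA half-width")),
            class = "meaningful_change_range")
}

#' Full agreement analysis of a reader table
#'
#' Convenience wrapper: paired differences, Bland-Altman statistics and the
#' Wilcoxon signed-rank p-value in one report.
#'
#' @inheritParams paired_differences
#' @return An `agreement_result` with an added `wilcoxon` element.
#' @export
agreement_analysis <- function(table, compare = c("readers", "sessions"),
                               scale = c("absolute", "relative"),
                               value = "mean_adc", reader = 1L) {
  compare <- match.arg(compare); scale <- match.arg(scale)
  d <- paired_differences(table, compare, scale, value, reader)
  res <- bland_altman(d, scale = scale)
  res$wilcoxon <- tryCatch(wilcoxon_signed_rank(d), error = function(e)
    list(statistic = NA_real_, p_value = NA_real_, n = 0L,
         method = conditionMessage(e)))
  res$compare <- compare
  res
}
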