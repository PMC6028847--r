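#' Configuration for a simulated two-reader lymph-node study
#'
#' Emulates the measurement structure of a volunteer study in which two
#' readers each segment every cervical lymph node twice on the same
#' acquisition. Each node has one true mean ADC and true volume (truncated
#' normals); a reader's measurement mixes the node's true ADC with
#' surrounding-tissue ADC according to that reader's segmentation
#' contamination fraction — over-inclusive contours pick up bright surround
#' voxels — plus measurement noise. Per-reader volume scale factors model
#' systematically larger/smaller contours.
#'
#' @param n_subjects number of volunteers (default 13).
#' @param nodes_per_subject nodes selected per volunteer (default 4; at
#'   least 4, with `n_nodes_total` allowing an exact overall count).
#' @param n_nodes_total optional exact total node count (e.g. 54); extra
#'   nodes beyond `n_subjects * nodes_per_subject` are assigned round-robin.
#' @param node_adc_mean,node_adc_sd true node-ADC distribution (mm^2/s),
#'   truncated at 0; defaults 0.87e-3 and 0.12e-3.
#' @param node_vol_mean,node_vol_sd true node-volume distribution (cm^3),
#'   truncated at 0; defaults 1.0 and 0.6.
#' @param surround_adc_mean,surround_adc_sd surrounding-tissue ADC
#'   distribution (mm^2/s); defaults 1.8e-3 and 0.3e-3 (bright,
#'   high-diffusivity tissue around the node).
#' @param contamination per-reader fraction of the VOI drawn from surround
#'   tissue, in `[0, 1)`; default `c(0, 0.053)` (reader 2 over-segments).
#' @param volume_scale per-reader multiplicative volume factor; default
#'   `c(1, 1.63)`.
#' @param noise_sd per-measurement ADC noise SD (mm^2/s); default 0.03e-3.
#' @param voxel_volume_mm3 voxel volume used to convert node volume to a
#'   voxel count (default 31.25 = 2.5 x 2.5 x 5 mm).
#' @return Object of class `reader_study_config`.
#' @export
reader_study_config <- function(n_subjects = 13L, nodes_per_subject = 4L,
                                n_nodes_total = NULL,
                                node_adc_mean = 0.87e-3, node_adc_sd = 0.12e-3,
                                node_vol_mean = 1.0, node_vol_sd = 0.6,
                                surround_adc_mean = 1.8e-3,
                                surround_adc_sd = 0.3e-3,
                                contamination = c(0, 0.053),
                                volume_scale = c(1, 1.63),
                                noise_sd = 0.03e-3,
                                voxel_volume_mm3 = 31.25) {
  if (any(c(node_adc_sd, node_vol_sd, surround_adc_sd, noise_sd) < 0))
    stop("all SDs must be >= 0")
  if (any(contamination < 0 | contamination >= 1))
    stop("contamination fractions must lie in [0, 1)")
  if (nodes_per_subject < 4L)
    stop("at least four nodes are selected per subject")
  if (length(contamination) != 2L || length(volume_scale) != 2L)
    stop("contamination and volume_scale must have one entry per reader")
  structure(list(
    n_subjects = as.integer(n_subjects),
    nodes_per_subject = as.integer(nodes_per_subject),
    n_nodes_total = if (is.null(n_nodes_total)) NULL else as.integer(n_nodes_total),
    node_adc_mean = node_adc_mean, node_adc_sd = node_adc_sd,
    node_vol_mean = node_vol_mean, node_vol_sd = node_vol_sd,
    surround_adc_mean = surround_adc_mean, surround_adc_sd = surround_adc_sd,
    contamination = contamination, volume_scale = volume_scale,
    noise_sd = noise_sd, voxel_volume_mm3 = voxel_volume_mm3),
    class = "reader_study_config")
}

#' Contamination fraction that injects a target inter-reader bias
#'
#' Solves, in expectation, for the reader-2 contamination fraction `f` such
#' that the Bland-Altman relative bias (reader 1 minus reader 2, pair-mean
#' denominator) equals `bias_pct` when reader 1 is contamination-free:
#' with `t` the node ADC and `s` the surround mean, reader 2 measures
#' `(1 - f) t + f s` and the relative bias is
#' `100 * (t - b2) / ((t + b2) / 2)`.
#'
#' @param bias_pct target relative bias in percent (negative when the
#'   surround is brighter than the node).
#' @param node_adc_mean,surround_adc_mean distribution means (mm^2/s).
#' @return Contamination fraction in `[0, 1)`.
#' @export
contamination_for_bias <- function(bias_pct, node_adc_mean = 0.87e-3,
                                   surround_adc_mean = 1.8e-3) {
  # bias = 100 (t - b2) / ((t + b2)/2)  with  b2 = t + f (s - t)
  # => f (s - t) = -bias/100 * (t + b2)/2 ; solve linearly for f
  q <- bias_pct / 100
  t <- node_adc_mean; s <- surround_adc_mean
  # (t - b2) = -f (s - t); (t + b2)/2 = t + f (s - t) / 2
  # -f d = q (t + f d / 2), d = s - t  =>  f = -q t / (d (1 + q / 2))
  d <- s - t
  f <- -q * t / (d * (1 + q / 2))
  if (f < 0 || f >= 1)
    stop("target bias not reachable with this surround distribution")
  f
}

rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) {
    bad <- x <= 0
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Simulate a two-reader, two-session lymph-node measurement table
#'
#' Each node's true ADC and volume are drawn once; every reader x session
#' measurement is
#' `(1 - f_r) * trueADC + f_r * mean(surround draws) + noise`,
#' where `f_r` is the reader's contamination fraction and the surround
#' draws model the bright tissue swept in by an over-inclusive contour.
#' Reader volumes are the true volume times the per-reader scale factor
#' (with small lognormal session jitter). With zero contamination and zero
#' noise all four measurements of a node are identical.
#'
#' @param config a [reader_study_config()].
#' @param seed integer seed; identical seed + config give an identical table.
#' @return data.frame with columns `subject`, `node`, `reader`, `session`,
#'   `volume_cm3`, `mean_adc`, `sd_adc` (one row per node x reader x
#'   session).
#' @export
simulate_reader_study <- function(config, seed = NULL) {
  stopifnot(inherits(config, "reader_study_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_nodes <- if (!is.null(config$n_nodes_total)) config$n_nodes_total
             else config$n_subjects * config$nodes_per_subject
  if (n_nodes < config$n_subjects * 4L)
    stop("n_nodes_total must allow >= 4 nodes per subject")
  subject <- rep(seq_len(config$n_subjects),
                 length.out = max(n_nodes, config$n_subjects))[seq_len(n_nodes)]
  subject <- sort(subject)
  node <- stats::ave(subject, subject, FUN = seq_along)
  true_adc <- rtruncnorm0(n_nodes, config$node_adc_mean, config$node_adc_sd)
  true_vol <- rtruncnorm0(n_nodes, config$node_vol_mean, config$node_vol_sd)
  rows <- vector("list", n_nodes * 4L)
  k <- 0L
  for (i in seq_len(n_nodes)) {
    for (r in 1:2) {
      f <- config$contamination[r]
      vol_r <- true_vol[i] * config$volume_scale[r]
      n_vox <- max(4L, round(vol_r * 1000 / config$voxel_volume_mm3))
      for (s in 1:2) {
        m <- (1 - f) * true_adc[i]
        if (f > 0) {
          n_sur <- max(1L, round(f * n_vox))
          m <- m + f * mean(rtruncnorm0(n_sur, config$surround_adc_mean,
                                        config$surround_adc_sd))
        }
        if (config$noise_sd > 0)
          m <- m + stats::rnorm(1, 0, config$noise_sd)
        vol_jit <- if (config$noise_sd > 0)
          vol_r * exp(stats::rnorm(1, 0, 0.05)) else vol_r
        k <- k + 1L
        rows[[k]] <- data.frame(
          subject = subject[i], node = node[i], reader = r, session = s,
          volume_cm3 = vol_jit, mean_adc = max(m, 1e-12),
          sd_adc = config$node_adc_sd * (1 + f))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "true_adc") <- true_adc
  attr(out, "seed") <- seed
  out
}
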