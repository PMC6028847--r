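#!/usr/bin/env Rscript
# Ice-water phantom quality control: simulate four repeat DWI acquisitions
# of a 0 degC water phantom (b = 0, 100, 600, 800 s/mm^2), fit the pairwise
# ADC maps, compute the six QC metrics against the published claim limits,
# and profile the spatial ADC bias along the horizontal and vertical axes.

suppressPackageStartupMessages(library(dwiqc))
dir.create("results", showWarnings = FALSE)
seed <- 20260928L

## 1. Quality control under realistic magnitude noise ----------------------
ex <- icewater_qc_experiment(noise_sd = 5, n_repeats = 4L, seed = seed)
cat("== Ice-water QC (Rician noise sd 5, 4 repeats) ==\n")
print(ex$report)

## 2. Noiseless validation run: the pipeline itself adds no bias -----------
ex0 <- icewater_qc_experiment(seed = seed)
cat(sprintf("\nNoiseless pipeline bias: %.3g%% (machine-level zero)\n",
            max(abs(ex0$report$metrics$bias_pct))))

## 3. Spatial bias: measured profiles and the fitted forward model ---------
profiles <- spatial_shift_profiles()
r_h <- pearson_correlation(profiles$x$distance_cm, profiles$x$rel_error_pct)
r_v <- pearson_correlation(profiles$y$distance_cm, profiles$y$rel_error_pct)
cat(sprintf("\nMeasured shift profiles: horizontal r = %.2f [%.2f, %.2f], vertical r = %.2f [%.2f, %.2f]\n",
            r_h$r, r_h$ci_low, r_h$ci_high, r_v$r, r_v$ci_low, r_v$ci_high))
cat("Only the vertical (downward) shift correlates with distance:\n")
cat("gradient non-linearity biases ADC increasingly below the isocentre.\n")

sim_prof <- bias_profile_experiment(bias = default_bias_field(),
                                    step_mm = 20, n_steps = 4)
cat("\nForward-simulated vertical profile under the fitted bias field:\n")
print(sim_prof$y$profile, digits = 3)

## outputs ------------------------------------------------------------------
m <- ex$report$metrics
write.csv(m, "results/icewater_qc_metrics.csv", row.names = FALSE)
write.csv(rbind(cbind(axis = "x", profiles$x), cbind(axis = "y", profiles$y)),
          "results/spatial_profiles_measured.csv", row.names = FALSE)
write.csv(cbind(axis = "y", sim_prof$y$profile),
          "results/spatial_profile_simulated.csv", row.names = FALSE)
write_report_json(list(
  metrics = m,
  b_dependence_pct = ex$report$b_dependence_pct,
  snr_ndyn = ex$report$snr,
  pearson_horizontal = r_h, pearson_vertical = r_v),
  "results/icewater_qc_report.json", seed = seed)
cat("\nWrote results/icewater_qc_metrics.csv, spatial_profiles_measured.csv,\n",
    "spatial_profile_simulated.csv, icewater_qc_report.json\n")
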