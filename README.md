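# dwiqc — reliability analysis for ADC mapping in diffusion-weighted MRI

The apparent diffusion coefficient (ADC, mm²/s) — the mono-exponential
decay rate of the diffusion-weighted MRI signal with b-value,
`S(b) = S0 · exp(−b · ADC)` — is a leading quantitative imaging biomarker
in oncology. Whether an ADC change in a patient means biology or
measurement error depends on the accuracy, repeatability, spatial
uniformity, target-size dependence and observer dependence of the whole
measurement chain. `dwiqc` implements that reliability analysis as a
tested, reproducible pipeline for medical physicists and imaging
scientists:

* **Synthetic acquisition** — voxelised phantom scenes (ice-water
  cylinder, six-sphere partial-volume phantom) rendered with sub-voxel
  compartment fractions, signal-domain partial-volume mixing,
  multiplicative gradient-nonlinearity bias fields, Rician noise and
  repeated dynamics; plus a two-reader lymph-node study simulator with a
  segmentation-contamination model.
* **ADC fitting** — the two-b-value closed form
  `ADC = ln(S(b_low)/S(b_high)) / (b_high − b_low)` and a multi-b
  log-linear fit, with low-signal masking as scanner software applies.
* **Quality control** — the six standard phantom metrics (repeatability
  CV and coefficient `RC = 2.77·σ_R`, bias vs the 0 °C water reference
  `1.1×10⁻³ mm²/s`, within-ROI noise estimate, b-value dependence,
  temporal SNR) flagged against claim thresholds, and spatial bias
  profiles with Pearson correlations.
* **Partial-volume analysis** — 80%-diameter VOI scaling across sphere
  sizes, concentric-VOI controls, and same-size differential
  measurements that isolate contamination exactly.
* **Observer agreement** — Bland-Altman bias and limits of agreement
  (absolute and relative), an exact tie-aware Wilcoxon signed-rank test,
  and a log-symmetric meaningful-change range derived from
  intra-observer reproducibility.

File formats: NIfTI-1 + FSL-style `.bval` for image series, YAML for
ROI/layout/threshold configuration, CSV for measurement tables, JSON for
reports.

## Worked example

Simulate four noisy repeat acquisitions of the ice-water phantom, fit the
pairwise ADC maps and run quality control:

```r
library(dwiqc)
ex <- icewater_qc_experiment(noise_sd = 5, n_repeats = 4, seed = 20260928)
ex$report
#> <qc_report>
#>   pair     mu_R   sigma_R  cv_pct        rc  bias_abs bias_pct noise_pct
#> 1 b100 0.001096 5.099e-06 0.46507 1.412e-05 -3.662e-06 -0.33292     6.694
#> 2 b600 0.001101 9.103e-07 0.08271 2.521e-06  5.554e-07  0.05049     1.701
#> 3 b800 0.001099 6.234e-07 0.05670 1.727e-06 -5.039e-07 -0.04581     1.522
#>   cv_pass rc_pass bias_pass noise_pass
#> 1    TRUE    TRUE      TRUE      FALSE
#> 2    TRUE    TRUE      TRUE       TRUE
#> 3    TRUE    TRUE      TRUE       TRUE
#> b-value dependence: 0.0962% (pass: TRUE)
#> SNR_nDyn: 222 (pass: TRUE)
```

Reading: each row is one b-value pair, e.g. `b800` is the ADC map fitted
from b = 0 and b = 800 s/mm². The repeat means sit within 0.4% of the
0 °C water reference (`bias_pct`), repeatability is far inside the 1.5%
claim (`cv_pct`), but the within-ROI noise estimate of the weakly
diffusion-weighted `b100` map (6.7%) exceeds its 2% claim — the same
qualitative failure pattern a physical phantom session shows. With the
noise turned off the pipeline's own bias is at machine precision
(`~4e-14 %`), and the temporal SNR becomes undefined (flagged, not
infinite) because all repeats are identical.

The shifted-ROI profile of the measured spatial bias data gives Pearson
r = 0.25 horizontally and r = 0.95 vertically: only vertical
(down-table) shifts carry a systematic gradient-nonlinearity error,
reaching 24.1% at 8 cm from the isocentre.

## The analysis workflow

Three numbered drivers under `analysis/` rerun the complete study and
write their tables to `results/`:

```sh
Rscript analysis/01_icewater_qc.R           # QC metrics + spatial bias profiles
Rscript analysis/02_sphere_partial_volume.R # scaling / concentric / differential VOIs
Rscript analysis/03_reader_agreement.R      # Bland-Altman, Wilcoxon, meaningful change
```

The methods vignette (`vignettes/adc-reliability.Rmd`) documents the
models, parameter choices and limitations.

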