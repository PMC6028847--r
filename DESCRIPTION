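Package: dwiqc
Title: Quality Control and Reliability Analysis for ADC Mapping in
    Diffusion-Weighted MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates diffusion-weighted MRI phantom acquisitions
    (ice-water and multi-sphere partial-volume phantoms, gradient
    non-linearity bias fields, Rician noise, repeated dynamics) and
    two-reader lymph-node measurement studies; fits apparent diffusion
    coefficient (ADC) maps by the two-b-value closed form or a
    log-linear multi-b fit; computes QIBA-style quality-control metrics
    (repeatability coefficient of variation, repeatability coefficient,
    bias, noise estimate, b-value dependence, temporal SNR) with
    pass/fail claims; quantifies spatial ADC bias profiles and
    partial-volume errors across sphere sizes; and runs Bland-Altman
    inter/intra-observer agreement, exact Wilcoxon signed-rank tests and
    a log-symmetric meaningful-change range.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
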