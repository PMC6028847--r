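---
title: "Quantifying the reliability of ADC measurements: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the reliability of ADC measurements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwiqc)
```

## The problem

The apparent diffusion coefficient (ADC, mm²/s) is the decay rate of the
diffusion-weighted MRI signal with b-value and a leading quantitative
imaging biomarker in oncology. Before an ADC change in a patient can be
read as biology, every step of the measurement chain — acquisition, map
fitting, region-of-interest (ROI) statistics, human segmentation — must be
characterised for accuracy and precision. `dwiqc` implements that full
characterisation as a reproducible pipeline: phantom-style quality control
against claim thresholds, spatial bias profiling, partial-volume analysis
across target sizes, and inter/intra-observer agreement statistics, all
runnable with no scanner because the package also ships the synthetic-data
generators that emulate each experiment.

## Signal model and ADC fitting

A voxel containing compartments $c$ with volume fractions $f_c$, proton
density $S_{0,c}$ and diffusivity $D_c$ produces, at b-value $b$,

$$S(b) = \sum_c f_c\, S_{0,c}\, e^{-b\, D_c\, (1+\varepsilon(\mathbf{p}))},$$

where $\varepsilon(\mathbf{p})$ is the multiplicative relative ADC error of
the gradient system at position $\mathbf{p}$ (zero at the magnet
isocentre). Two modelling choices matter:

* **Partial volume mixes signals, not ADCs.** The scanner integrates
  magnetisation over the voxel, so `rasterize_scene()` stores sub-voxel
  compartment fractions (default `supersample = 5` per axis, i.e. 125
  sub-voxel samples) and `synthesize_dwi()` sums the compartment decays.
  Fitting a mono-exponential to such a mixed signal is exactly what
  produces the non-linear small-target errors the sphere analysis
  quantifies; averaging ADCs instead would hide them.
* **Bias is multiplicative on ADC.** Gradient non-linearity rescales the
  effective b-value, so the measured ADC is $D(1+\varepsilon)$. This
  matches the relative-percent form in which shifted-ROI errors are
  reported, and makes the round-trip property exact: for noiseless data
  the fitted map satisfies $\widehat{D}(\mathbf{p})/D - 1 =
  \varepsilon(\mathbf{p})$ (tested at 1e-9).

`compute_adc_pair()` is the scanner-console closed form
$\mathrm{ADC} = \ln(S(b_\mathrm{low})/S(b_\mathrm{high})) / (b_\mathrm{high}-b_\mathrm{low})$;
`compute_adc_loglinear()` generalises it to an ordinary least-squares fit of
$\ln S$ on $b$ and reduces bit-for-bit to the pairwise form for two
b-values. Voxels whose signal does not exceed `signal_floor` are masked
invalid — never zero-filled, because zeros would silently corrupt ROI
means. The default floor is 0 (all positive signals used): clinical
post-processing packages do threshold low-intensity voxels, but no
portable threshold value exists, so it is a parameter rather than a
constant.

Noise is Rician, $\sqrt{(v+g_1)^2+g_2^2}$ with independent Gaussians of SD
$\sigma$, the correct magnitude-MRI model; a Gaussian option exists for
analytic checks. At $v=0$ the output mean is the Rayleigh mean
$\sigma\sqrt{\pi/2}$ and at $v \gg \sigma$ it converges to $v$; both limits
are property-tested.

## Quality-control metrics

From four repeat acquisitions of an ice-water phantom (0 °C water has the
known reference $DC_\mathrm{True} = 1.1\times10^{-3}$ mm²/s) the package
computes, per b-value pair:

| metric | definition |
|---|---|
| $CV_R$ | $100\,\sigma_R/\mu_R$, over repeat ROI means |
| $RC_R$ | $2.77\,\sigma_R$ (the literal published constant, not $1.96\sqrt2$) |
| bias | $\mu - DC_\mathrm{True}$, also as % of $DC_\mathrm{True}$ |
| noise estimate | $100\,\sigma/\mu$ within a single ROI |
| b-value dependence | $100\,\lvert(\mathrm{ADC}_{b0,b800}-\mathrm{ADC}_{b0,b600})/\mathrm{ADC}_{b0,b600}\rvert$ |
| $SNR_{nDyn}$ | ROI mean of the temporal-mean image over ROI mean of the temporal-SD image at $b=0$ |

Claim thresholds default to the published limits ($CV_R<1.5\%$,
$RC_R<1.5\times10^{-5}$, $|$bias$|<3.6\%$, noise $<2\%$, b-dependence
$<2\%$, $SNR\ge50$) and are compared with the printed strict inequalities:
boundary equality fails. Conventions the source material leaves open were
fixed once: sample (n−1) standard deviations everywhere, in line with
standard repeatability practice; the $SNR_{nDyn}$ formula is implemented
literally, without the $c_4$ small-sample SD-bias correction (the
$c_4$-aware expectation appears only in test tolerances); Pearson
correlations carry Fisher-z confidence intervals. On identical repeats the
temporal noise image is exactly zero, so the SNR is reported as undefined
(`NA` plus a note) rather than infinite — this is what a noiseless
validation run produces.

## Spatial bias profiling

`shifted_roi_series()` walks an ROI along one axis and reports each mean's
relative deviation from the isocentre value; `spatial_profile()` adds the
Pearson correlation of deviation with distance. The package ships the
measured shift profiles (flat horizontally out to 18 cm, rising to 24.1% at
8 cm vertically) both as replay data and, through `fit_bias_field()`
(least-squares polynomial, zero intercept, default degree 2), as the
default forward-simulation field.

One numerical subtlety: an ROI of radius $r$ averages the field over its
footprint, which for a quadratic field inflates the profile by
$\approx c_2 r^2/4$. The profiling experiments therefore default to a small
(8 mm) ROI so the series tracks the field value at the ROI centre; with a
22 mm ROI the smoothing term would be of the same order as the 0.1%
recovery tolerance.

## Sphere-phantom partial-volume analyses

The six-sphere layout (10, 13, 17, 22, 28, 37 mm diameters on a ring
around the isocentre) is rendered at the clinical voxel size
(2.5 × 2.5 × 5 mm) with room-temperature water spheres
($D = 2.0\times10^{-3}$ mm²/s; the physical experiment is relative, so
only contrasts matter) in a low-signal solid background (S0 at 10% of
water, $D = 0.3\times10^{-3}$ mm²/s). The background values are a design
choice — the physical insert material is not specified anywhere — picked
so that edge contamination visibly perturbs small-sphere VOIs, which is
the phenomenon under study. The direction of the small-sphere error
depends on that choice; the analyses therefore assert magnitudes and
orderings, not signs.

Three analyses, all VOI-based (strict centre-inclusion voxel selection):

1. **Scaling** (`scaling_analysis()`): one VOI per sphere at 80% of the
   sphere diameter, floored at 10 mm (below that a VOI holds only a
   handful of clinical voxels); relative error versus the 37-mm reference
   sphere and CV across repeat days. Repeats are averaged before the
   relative error is taken.
2. **Concentric control** (`concentric_voi_analysis()`): shrinking VOIs
   all centred in the reference sphere. Deviations stay within noise —
   VOI size alone is benign; this separates size effects from
   contamination.
3. **Differential same-size** (`differential_same_size_analysis()`): the
   80%-rule VOI measured in its target sphere *and* an identically sized
   VOI in the reference sphere; the absolute relative error between the
   two isolates partial-volume contamination exactly, because both VOIs
   share size, shape and voxel count. On a phantom with the background
   contrast removed these errors vanish to machine precision — a strong
   end-to-end test of the whole chain.

## Reader-study simulation and agreement statistics

`simulate_reader_study()` emulates a two-reader, two-session study of
cervical lymph nodes: 13 subjects, ≥4 nodes each (54 nodes total in the
standard configuration), true node ADC drawn once per node from a
truncated normal (mean 0.87 × 10⁻³, SD 0.12 × 10⁻³ mm²/s), volumes around
1 cm³. Each reader×session measurement is

$$(1-f_r)\,D_\mathrm{node} + f_r\,\overline{D}_\mathrm{surround} + \eta,$$

with $f_r$ the reader's segmentation-contamination fraction,
surround-tissue ADC drawn per measurement (mean 1.8 × 10⁻³ mm²/s —
nodes sit in heterogeneous bright tissue), and $\eta$ measurement noise
(SD 0.03 × 10⁻³ mm²/s, chosen to give intra-observer limits of agreement
near ±10%, the observed scale). The node component enters through its true
mean rather than per-measurement voxel redraws so that the zero-noise,
zero-contamination limit yields exactly identical repeated measurements.
`contamination_for_bias()` inverts the model in expectation: for a target
inter-reader relative bias of −5.5% it returns $f_2 \approx 0.053$.
Per-reader volume scale factors (default 1 and 1.63) reproduce systematic
over-segmentation by the junior reader.

Agreement statistics follow Bland-Altman: bias = mean paired difference,
limits of agreement = bias ± 1.96 SD (sample SD; the 1.96 convention, not
2). Relative differences use the pair mean as denominator — standard for
ratio-scale data; the alternative single-reader denominator differs only
in the second decimal at these effect sizes. Nodes are treated as
independent units, as an n = 54 analysis implies. The Wilcoxon signed-rank
test is implemented in-package: zeros dropped, mid-ranks for ties, exact
null distribution by generating-function convolution for n ≤ 25 (exact
even with ties, which `stats::wilcox.test` refuses), and a
continuity-corrected normal approximation with tie-corrected variance
above; it is cross-checked against full 2ⁿ sign-pattern enumeration and
against `stats::wilcox.test` where the latter is exact.

The meaningful-change range maps the intra-observer LoA half-width $h$ (%)
through $c = \sqrt{2}\,h/100$ — a longitudinal change compares two noisy
measurements — treated as a log-scale limit:
$[100(e^{-c}-1),\ 100(e^{c}-1)]$. The published formulation behind the
range is not fully specified, so this reconstruction (which reproduces the
reported [−13%, +15%] from LoA [−9.2%, 10.4%]) is isolated in one function
and labelled as such in its output.

## What the generators do and do not emulate

The synthetic phantoms reproduce the statistical structure the analyses
assume: known true diffusivities, signal-domain partial volume, smooth
multiplicative spatial bias, Rician noise, independent repeats, and
reader-level segmentation contamination. They deliberately omit EPI
distortion, eddy currents, motion, T2 shine-through, temperature drift and
scanner-specific reconstruction filters. Passing tests therefore validate
the *analysis chain* — that each statistic measures what it claims under a
known ground truth — not the claim that any particular scanner meets the
thresholds; measured phantom values from real hardware cannot be
regenerated from first principles.

Two printed-geometry details are knowingly irreproducible and left as
configuration rather than constants: the reported 123-voxel count for a
2.5-cm ROI (every standard centre-inclusion rule on a 2-mm grid gives 121,
which the lattice-oracle tests pin down), and the exact clinical in-plane
matrix (never printed; an 8-voxel 10-mm VOI implies coarser voxels than
2 mm). Two cells of the published scaling table (the 17- and 13-mm
spheres) are inconsistent with their own printed means at the stated
rounding and are excluded from numeric reproduction.

## Numerical choices and problem sizes

Default grids are 120 × 120 × 3 voxels at 2 × 2 × 4 mm for the ice-water
experiments and 80 × 80 × 12 at 2.5 × 2.5 × 5 mm for the sphere phantom —
small enough that a full experiment (rasterise, synthesise 4 repeats, fit,
analyse) runs in well under a second while keeping ROI voxel counts in the
regime of the physical measurements. Rasterisation uses strict inside
tests on sub-voxel centres; ROI selection uses strict centre inclusion
(boundary ties excluded as measure-zero). Voxel centres sit at
half-integer offsets from the grid origin, world coordinates are mm with
the isocentre at the origin, and all geometry shares this single
convention. Determinism is part of every generator's contract: the same
seed and configuration produce bit-identical outputs.

## Limitations

* The bias-field model is a separable per-axis polynomial; real gradient
  non-linearity fields have cross terms. For profile replay and recovery
  along a single axis this is exact.
* The reader simulator draws nodes independently; within-subject
  correlation of node ADCs is not modelled, matching how the agreement
  analysis treats nodes.
* Overlap checking of cylinders uses a conservative bounding test; scenes
  mixing many tangent cylinders may be rejected despite being valid.
* No absolute calibration exists for the room-temperature sphere phantom;
  all sphere analyses are relative by construction.
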