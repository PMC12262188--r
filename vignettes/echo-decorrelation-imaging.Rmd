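---
title: "Echo decorrelation imaging and closed-loop ablation control: models and methods"
author: "echodecorr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Echo decorrelation imaging and closed-loop ablation control: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echodecorr)
```

## The problem

Radiofrequency ablation (RFA) destroys tissue by resistive heating around a
deployed needle electrode. Treatment adequacy is hard to judge in real time:
B-mode ultrasound shows heated tissue poorly. *Echo decorrelation imaging*
exploits the millisecond-scale loss of correlation between sequential
complex (IQ) pulse-echo volumes that heat-induced transient changes --
coagulation, micro-motion, cracking, bubble activity -- produce. Mapping
that decorrelation voxel by voxel yields a 3D image of where tissue is
changing, which can both predict the final ablation zone and drive a
closed-loop controller that switches the generator off once a target region
has decohered.

This package implements the full chain as reusable, tested components:

1. a seeded synthetic generator of paired IQ echo volumes on a phased-array
   sector geometry with a known, growing decoherence region
   (`simulate_trial()`),
2. scan conversion and the combined-normalized decorrelation map
   (`scan_convert()`, `windowed_correlations()`,
   `instantaneous_decorrelation()`, `update_cumulative()`),
3. the threshold feedback controller and UC/SC/USC trial classification
   (`run_trial()`),
4. ablation-zone metrics (`sphere_mask()`, `mask_volume_ml()`, `dice()`,
   `section_and_reconstruct()`),
5. voxelwise prediction assessment (`roc_analysis()`, `pr_analysis()`,
   `min_achievable_aupr()`, `effective_fraction()`, `compare_auroc()`,
   `compare_aupr_bootstrap()`), and
6. outcome statistics on trial tables (`success_rates()`,
   `group_compare()`, `simple_regression()`, `tissue_regression()`).

## The decorrelation model

Each acquisition captures two echo volumes $I_0$, $I_1$ separated by
$\tau = 50$ ms. After scan conversion to an isotropic Cartesian grid
(60 mm extent, $l = 0.5$ mm pitch by default), zero-lag spatially windowed
correlations are formed with an isotropic 3D Gaussian window of width
parameter $\sigma = 3$ mm:

$$R_{01}(\mathbf r) = \sum_{\mathbf r'} w(\mathbf r - \mathbf r')\,
  I_0(\mathbf r')\, I_1^*(\mathbf r'), \qquad
  \beta^2(\mathbf r) = R_{00}(\mathbf r)\, R_{11}(\mathbf r),$$

and the instantaneous decorrelation per millisecond is

$$\Delta_{\mathrm{inst}}(\mathbf r) =
  \frac{2\left[\beta^2(\mathbf r) - |R_{01}(\mathbf r)|^2\right]}
       {\tau \left[\beta^2(\mathbf r) + \overline{\beta^2}\right]},$$

with $\overline{\beta^2}$ the spatial average of $\beta^2$. The combined
normalization bounds the map to $[0, 2/\tau]$ (Cauchy--Schwarz) and damps
spurious decorrelation where echo energy is low. The per-trial *cumulative*
map is the running temporal maximum of $\Delta_{\mathrm{inst}}$ at each
voxel; its log10 is the quantity thresholded by the controller and scored
against ablation masks.

For a homogeneous pair in which per-voxel coherence is $\rho$, the expected
spatial mean of $\Delta_{\mathrm{inst}}$ is $(1-\rho^2)/\tau$; the test
suite verifies recovery within 10% for $\rho^2 \in \{0, 0.5, 0.9\}$ and,
through the full sector-geometry pipeline, within 15% at 30 dB SNR.

### Numerical choices

* **Windowing** is a separable convolution with 1D Gaussian kernels
  truncated at $4\sigma$ (truncated mass $< 10^{-4}$) and normalized to
  unit sum; the normalization cancels in the ratio, which the tests assert
  directly.
* **Edge correction.** Zero-padded window sums shrink near the sector edge
  and the grid boundary, which depresses $\overline{\beta^2}$ and inflates
  central decorrelation by 15--18% on desk-scale grids. By default each
  window sum is renormalized by the local weight mass over valid voxels
  (normalized convolution); `edge_correction = FALSE` restores the raw
  sums used by the direct-summation oracle in the tests.
* **$\overline{\beta^2}$** averages over valid (imaged) voxels only, since
  the sector does not cover the cube's corners; `beta_bar_mode = "full"`
  averages over the whole cube with zero-filled invalid voxels for strict
  full-cube replication.
* **Scan conversion** uses trilinear interpolation under a separable-angle
  sector convention (azimuth angle in the y--z plane, elevation angle in
  the x--z plane, range along the beam), with the apex 30 mm before the
  grid center so the needle tip sits at the grid center at about 30 mm
  range. Correlations are computed after scan conversion, following the
  processing order of the emulated system; interpolation slightly smooths
  the maps, which the recovery tolerances absorb.
* **Degenerate inputs** error loudly: an all-invalid volume, a zero
  $\overline{\beta^2}$, an empty control ROI, groups without both classes,
  constant outcome columns, and rank-deficient regression designs are all
  rejected rather than silently patched.

## The synthetic trial generator

No raw IQ data are redistributable, so every downstream stage is exercised
on synthetic trials with analytically known ground truth.

* **Speckle.** Fully developed speckle is drawn as an iid circular complex
  Gaussian field on the beam sampling, smoothed by a separable Gaussian
  point-spread kernel (axial/lateral FWHM 0.3 / 1.7 mm, the B-mode
  resolution of the emulated matrix array, converted to sample units at
  mid-depth), then rescaled to unit mean squared magnitude.
* **Decoherence field.** Ground truth is a per-voxel cumulative coherence
  $\rho(\mathbf r, t) \in [0,1]$ on the Cartesian grid: 1 outside the
  lesion, falling along a raised-cosine radial profile to a configurable
  floor at the core. The nominal lesion radius grows linearly from 0 to
  the target radius (default 20 mm diameter, the standard clinical target
  emulated here) over `growth_duration_s`, then saturates. The profile's
  half-coherence crossing sits exactly at the nominal radius, so the mask
  rule -- a voxel is "ablated" when its final compounded coherence is at
  most 0.5 -- reproduces the targeted sphere (4.19 ml at 20 mm) to within
  voxelization error.
* **Evolution.** Between consecutive acquisitions the scatterer field is
  mixed with fresh speckle so that each voxel's coherence multiplies by the
  interval ratio $g_n = \rho(t_n)/\rho(t_{n-1})$; compounding therefore
  telescopes exactly to the ground-truth field, a property asserted to
  1e-10. The within-pair (50 ms) coherence is
  $g_n^{k\,\tau/T}$ with $T$ the 22 s cadence and $k$ the *transience
  exponent*. The default $k = T/\tau$ (i.e. $\rho_{\mathrm{pair}} = g_n$)
  models heat-induced change as fully transient -- visible within the
  50 ms pair -- which is what the decorrelation mechanism measures; $k = 1$
  would instead model change accrued uniformly in time, whose 50 ms
  signature is far below the control threshold and leaves the controller
  inert. The pipeline treats $k$ (as a fraction of the default) as a
  per-trial biological variability knob.
* **Noise** is additive circular complex Gaussian at a configurable SNR
  (default 30 dB) and affects only the echoes, never the truth mask.
* **Seeding.** All draws derive from one master seed through a
  counter-based hash, so any sub-stream (a single acquisition's fresh
  speckle, a single noise draw) is reproducible in isolation and
  regeneration is bit-identical.

What the generator does *not* emulate: acoustic propagation and
attenuation, thermal (bioheat) lesion dynamics, tissue-type-specific
acoustic properties, respiratory or probe motion, and reverberation or
shadowing artifacts. Passing tests on these synthetics therefore
demonstrate correctness of the measurement and control chain, not clinical
performance on real livers; the real study's headline areas under curves
depend on ex vivo data that are inputs, not reproducible claims, here.

## The feedback controller

At each 22 s acquisition the cumulative map is updated and the spatial
average of cumulative decorrelation over a 20 mm-diameter spherical control
ROI at the needle tip is compared, on the log10 scale, with the control
threshold (default $-2.8\ \log_{10}\mathrm{ms}^{-1}$, the 90%-specificity
operating point of the emulated study). A controlled trial that reaches the
threshold before the generator cycle ends stops there (*successfully
controlled*, SC); one that never reaches it runs to completion
(*unsuccessfully controlled*, USC); uncontrolled (UC) trials always
complete the cycle.

Two readings of "average log-scaled decorrelation" are defensible and both
are implemented: `mean-then-log` (default; log10 of the ROI mean of linear
values, matching a final ROI-average that is then log-scaled) and
`log-then-mean`. The threshold comparison is `>=`: at discrete 22 s checks
the distinction between "reaching" and "exceeding" is immaterial, but a
fixed rule keeps the boundary case deterministic, and the boundary test
pins it.

## Prediction assessment

Voxelwise scores (log10 cumulative decorrelation; zero-decorrelation voxels
floored one decade below the smallest positive score) are pooled per group
within a 25 mm-radius evaluation ROI and compared against ablation masks.

* ROC and PR curves are built over all distinct thresholds with ties
  grouped; AUROC by trapezoid equals the tie-corrected Mann--Whitney
  statistic (asserted against brute-force pair counting, and against an
  independent ROC implementation).
* The ROC-optimal threshold maximizes Youden's $J$; the PR-optimal
  threshold maximizes $F_1$, which at any threshold equals the Dice overlap
  of the thresholded map with the truth mask (asserted voxelwise). The
  90%-specificity cutoff is the smallest threshold with specificity at
  least 0.90, breaking ties toward higher sensitivity.
* AUPR is integrated by trapezoid over the empirical stepwise curve (an
  average-precision sum is available via `method`); because AUPR is
  floored by the class skew, `min_achievable_aupr()` reports the
  unachievable region $1 + (1-\pi)\ln(1-\pi)/\pi$, negligible for
  $\pi \le 0.1$ (the geometric skew of a 20 mm target inside the 25 mm
  evaluation ROI is 0.064).
* Voxels within one correlation window are not independent predictions;
  significance tests rescale to the effective count
  $N_{\mathrm{eff}}/N_{\mathrm{tot}} = \sqrt{2 (l/d)^3}$ with
  $d = 2.355\sigma$ the window FWHM (0.0266 at the default grid and
  window). The scaling is applied by evaluating the Hanley--McNeil AUC
  variance at $N_{\mathrm{eff}}$ counts (proportions preserved), since
  standard errors scale as $1/\sqrt N$; a `z_factor` mode that multiplies
  the full-count Z by $\sqrt{N_{\mathrm{eff}}/N_{\mathrm{tot}}}$ is kept
  for comparison, as the two conventions differ slightly through the
  finite-sample variance terms. AUPR differences use a seeded bootstrap
  (5000 draws by default) with the bootstrap SE inflated by
  $1/\sqrt{N_{\mathrm{eff}}/N_{\mathrm{tot}}}$.

## Outcome statistics

Trial tables (one row per trial: tissue condition, control condition,
gender, ablated volume, ablation rate, Dice against the target, final ROI
log-decorrelation, duration) are analyzed as the emulated protocol
prescribes: Shapiro--Wilk normality and Bartlett variance screens route
each outcome to either three-factor ANOVA (type-II sums of squares, suited
to the unbalanced, incomplete design) with Tukey HSD post hocs, or
per-factor Kruskal--Wallis tests with Dunn's post hoc (Bonferroni family =
all pairwise comparisons within the significant factor). Success
proportions are compared with pairwise 2x2 Pearson chi-squared tests
without continuity correction by default (the correction is selectable);
variance contrasts use the two-sample F test; and the volume/rate/Dice
outcomes are regressed on the final ROI log-decorrelation alone and
together with binary steatosis and cirrhosis indicators. Every test is
calibrated under its own simulated null to a type-I error within
[0.03, 0.07] at $\alpha = 0.05$ in the acceptance suite.

## Problem sizes

The package defaults mirror the emulated acquisition (85 x 67 lines x 485
samples over 90 deg x 90 deg to 70 mm; 121^3 Cartesian voxels at 0.5 mm).
The test and acceptance suites run the same code on reduced sizes chosen
for desk-scale runtimes -- typically a 121 x 33 x 25 beam geometry, a 41^3
grid at 1 mm, 11 acquisitions per trial, and batches of up to 30 trials --
with Monte Carlo calibrations at 500 replicates. These sizes are stated
here so that reported tolerances are read against the variance they imply;
all of them can be scaled up through the run configuration without code
changes.

## Known limitations

* The decoherence field is a geometric convenience (raised-cosine sphere),
  not a physical heating model; growth timing and profile parameters are
  not claims about tissue physics.
* Histology emulation samples each slab's mid-plane; real sectioning
  integrates discoloration through the slab and adds registration error.
* The AUC variance model is the distribution-free Hanley--McNeil form;
  paired-curve covariance (same voxels under two maps) is out of scope, as
  groups here are independent pools.
* In vivo confounders (respiratory motion, perfusion) and their artifact
  corrections are not modeled.
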