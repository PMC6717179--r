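---
title: "Methods: quantifying reconstruction-weighting effects on CT radiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying reconstruction-weighting effects on CT radiomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Adaptive statistical iterative reconstruction (ASIR) is a hybrid CT
reconstruction that blends filtered back projection (FBP) with iterative
denoising at a user-selected percentage weighting; 0% is pure FBP and
higher weightings progressively suppress image noise. Radiomics features —
quantitative descriptors of the intensity distribution and spatial texture
of a tumour region of interest (ROI) — are sensitive to that noise level,
so the same tumour imaged once and reconstructed at different weightings
yields systematically different feature values. `asirtex` implements a
complete pipeline for quantifying this effect: feature extraction from
six-weight reconstruction series (0, 20, 40, 60, 80, 100%), a synthetic
phantom cohort that emulates the reconstruction-driven noise reduction,
and a two-level regression model that expresses each feature's change per
20% weighting increment as an absolute coefficient and a standardised
effect size.

## Study design the pipeline mirrors

Each subject contributes one CT acquisition reconstructed at the six
weightings; a free-hand tumour ROI is drawn on the 0% series and copied
unchanged onto the other five, which is valid only when all six volumes
share one voxel grid. Grid congruence is therefore enforced strictly
(shape identical, spacing within 1e-6 mm, origin within 1e-3 mm) and any
mismatch excludes the subject — mirroring how spatial mismatches are
handled in practice — rather than being repaired by resampling.

Two analysis modes are derived per subject:

* **single-slice (2D)** — the axial slice with the largest tumour area
  (ties broken to the lowest slice index);
* **multi-slice (3D)** — the contiguous 5-slice window, each slice
  containing tumour, that maximises total tumour coverage (ties to the
  lowest start index). Tumours not segmentable on 5 consecutive slices
  contribute single-slice analysis only.

The tie-breaks and the maximal-coverage window placement are package
choices; nothing in the study design pins them down, and determinism
requires fixing them.

## Preprocessing

A "medium" smoothing filter and a 32-bin grey-level discretisation precede
extraction. These are implemented as:

* **Smoothing** — an in-plane 3x3 mean filter with replicated edges
  (`smooth_volume()`, configurable to Gaussian or median and to other odd
  sizes). "Medium" is read as a strength setting of an unspecified kernel;
  a 3x3 mean is the most conservative reading. Smoothing is applied to the
  whole slice before masking.
* **Discretisation** — `level = 1 + floor(Ng (v - min)/(max - min))`
  clipped to `[1, Ng]` with `Ng = 32` bins over the ROI's own intensity
  range (`discretise()`). The phrase "32 bin width" is ambiguous between a
  bin *count* of 32 and 32-HU-wide bins; the fixed bin count is the
  default because it bounds every texture-matrix dimension, and a
  `fixed_width` mode is provided for sensitivity analyses. The min/max are
  recomputed per region and per weight (no cross-series locking), matching
  per-dataset extraction. First-order moment statistics use the smoothed
  HU values directly; histogram energy/entropy and all texture matrices
  use the 32-level discretisation.

## The 70 features

* **First-order (10)** — mean, maximum, minimum, range, SD, coefficient of
  variation, skewness, kurtosis, energy, entropy. SD uses the sample
  (n-1) denominator; skewness/kurtosis use population moments with
  kurtosis non-excess (a Gaussian scores about 3); entropies throughout
  the package are base 2 with `0 log 0 := 0`.
* **GLCM (19)** — symmetric co-occurrence matrices at voxel distance
  `d = 1`, one per direction (4 in-plane directions in 2D; 13 unique
  3D directions), features averaged over directions.
* **GLDM (4)** — the grey-level *difference* matrix (the distribution of
  `|i - j|` over the same voxel pairs), mean/entropy/variance/contrast.
  GLDM is aggregated per direction exactly like the GLCM so that the
  structural identities `GLDM mean = GLCM dissimilarity` and
  `GLDM contrast = GLCM contrast` hold exactly on every input (a pooled
  histogram would weight directions by pair count and break them at mask
  edges).
* **NGTDM (5)** — Amadasun-King coarseness, contrast, busyness,
  complexity, texture strength over 8- (2D) or 26-neighbourhoods (3D).
  Coarseness is guarded as `1/(1e-6 + sum p_k s_k)`, so a perfectly
  uniform region returns 1e6 instead of infinity.
* **GLRL (13)** — run-length features per direction, averaged. The
  non-standard names "intensity variability" and "run length variability"
  are implemented as the *normalised* grey-level and run-length
  non-uniformities; this is an interpretation (no formula is published for
  them) and is flagged as such.
* **GLZSM (13)** — zone-size features over connected components of equal
  level (8-connectivity in 2D, 26 in 3D), with the same normalised
  reading of "intensity variability"/"size zone variability".
* **Fractal (6)** — computed in single-slice mode only (the 3D analysis
  of these features is out of scope, consistent with their absence from
  the multi-slice results): fractal dimension mean and SD, lacunarity,
  Hurst exponent, blanket mean and max.

Everywhere the masked-edge rule applies: a pair, neighbour, run step or
zone link exists only when both voxels are inside the mask.

## Fractal estimators

The intensity surface is the smoothed single-slice ROI on its bounding
box, shifted non-negative by subtracting the ROI minimum (the fractal
dimension is scale-free and the blanket features are shift-invariant, so
this changes nothing but keeps the surface interpretable as a terrain).

**Fractal dimension** uses differential box counting per sliding 8x8
window with box sizes {2, 4, 8}: the FD is the least-squares slope of
`log N(s)` against `log(1/s)`, and `fd_mean`/`fd_sd` summarise windows
centred on masked pixels. The column-height count per box is
`max(1, (sd_box/sd_window) * window/s)` — a dispersion-referenced height
rather than the classical max-min range. In windows this small the range
of a 2x2 box is a heavily biased estimate of vertical extent (an
extreme-value effect that pushes all estimates towards 2), whereas the
sample SD of a self-affine surface scales cleanly as `s^H`; with the
dispersion height the estimator returns exactly 2 on flat patches and
tracks the theoretical `FD = 3 - H` on synthetic fractional Brownian
surfaces within the tolerances asserted in the test suite. Estimates are
clamped to `[2, 3]`; windows with identical counts at all scales are
skipped as degenerate.

**Lacunarity** is the gliding-box statistic `Lambda(r) = E[M^2]/E[M]^2`
over box masses `M` (sums of discretised levels) for boxes fully inside
the mask, averaged over `r` in {2, 4, 8, 16}. It is 1 exactly for
spatially constant mass and always >= 1 and strictly positive, which is
why the effect model can analyse it on the log scale.

**Hurst exponent** is derived deterministically as `H = 3 - fd_mean`
rather than re-estimated (e.g. by rescaled range). The two features are
then exactly antisymmetric under regression — coefficients equal in
magnitude and opposite in sign — which is the behaviour the reported
effect tables display.

**Blanket features** follow the Peleg construction: upper/lower envelopes
grown by iterated grey-scale dilation/erosion with a cross-shaped
structuring element, surface area `A(eps) = sum(u_eps - b_eps)/(2 eps)`
for `eps = 1..8`, summarised by mean and max. Blanket mean and max are
implemented as genuinely distinct quantities even though they can
coincide on smooth surfaces.

## The synthetic phantom cohort

No imaging data are distributed, so the cohort generator is a first-class
module: it emulates the *statistical structure* the analysis assumes, not
CT physics. Per subject: an ellipsoidal tumour (in-plane radius 24-28
voxels, i.e. roughly a 5 cm tumour at ~1 mm in-plane resolution; 5-7
axial slices of 5 mm, with 5 of 28 subjects spanning only 2-4 slices to
exercise the multi-slice exclusion) on a darker background, carrying a
subject-level mean (80 +/- 15 HU between subjects), a spatially correlated
texture field (Gaussian-smoothed white noise, correlation length 2
voxels, SD 12 HU) and i.i.d. noise of SD 30 HU.

The proprietary reconstruction is emulated, not reimplemented: the volume
at weight `w` is the convex blend
`v_w = (1 - lambda(w)) noisy + lambda(w) smoothed(noisy)` with a Gaussian
sigma-1.5 smoothed copy, so all six weights share one realisation and
differ only by progressive reconstruction-like smoothing. Two generator
choices deserve explanation:

* **The blend schedule is `lambda(w) = 0.85 w/100`**, not `w/100`. The
  masked noise variance of a convex blend is quadratic in `lambda` with
  its minimum essentially at `lambda = 1`; driving the top weighting all
  the way to the fully smoothed copy makes the final 80 -> 100% step
  produce no measurable noise change, and range-renormalised texture
  features then plateau instead of progressing. Capping the blend keeps
  the emulated noise reduction strictly progressive across all six
  weights — the phenomenology the generator exists to reproduce — and is
  also physically reasonable: the highest weighting reduces, but does not
  eliminate, noise.
* **Noise has bounded support** (uniform, matched SD) rather than
  Gaussian tails. Because discretisation re-bins each weight over its own
  ROI min/max, the bin width tracks the ROI *extremes* while the texture
  signal tracks the bulk SD; Gaussian extreme-value jitter makes the
  range contract erratically relative to the SD and injects
  non-monotone level-map noise into sparse texture statistics (GLCM
  energy is the most fragile). Bounded support pins the extreme-to-SD
  ratio and keeps the per-weight response clean at desk scale.

What the phantom does *not* emulate: CT projection physics, beam
hardening, slice-direction texture correlation (slices are independent,
consistent with 5 mm reconstructions), contrast kinetics, and clinically
calibrated effect magnitudes. Passing the pipeline's tests on the phantom
therefore demonstrates correctness of the machinery and the qualitative
response directions (noise-sensitive features fall, smoothness-sensitive
features rise, 3D features move less than 2D), not the clinical effect
sizes; standardised effect sizes measured on the phantom are larger than
those reported for patient data. A second consequence: the blend response
is mildly curved in `w`, so the shape-selection step frequently and
correctly retains quadratic terms on phantom data, whereas clinical
reports found simple linear relationships adequate.

`simulate_feature_table()` generates feature tables directly from the
two-level model (`y_ij = mu + u_i + beta x + gamma2 x^2 + gamma3 x^3 +
e_ij`, `x = w/20`) for testing the effect model in isolation with known
truth, and `fbm_surface()` synthesises fractional Brownian surfaces —
using the discrete frequency response `2 sin(pi f)` in place of `f` so
increment scaling holds down to the pixel scale — as the known-roughness
oracle for the fractal estimator.

## The effect model

Each feature (per analysis mode) is regressed on ASIR weight with a
two-level random-intercept model: measurements nested within subjects,
REML estimation (`lme4`), Wald normal tests and confidence intervals.
Weight is coded `x = w/20` so the linear coefficient is directly the
change per 20% increment. Shape selection starts from a cubic polynomial
and sequentially drops the cubic, then the quadratic term when
non-significant at alpha = 0.05, leaving a simple linear relationship
otherwise. Fractal lacunarity is analysed on the log scale by default
(its distribution is strongly right-skewed; positivity is guaranteed by
construction); the log-feature list is configurable and no automatic
skewness trigger is applied.

The standardised effect size is `B = |coef| / sigma_b` with `sigma_b` the
between-subject SD, by default the model's random-intercept SD (a
`raw_subject_means` alternative is provided; which variant the original
analysis used is not documented). Categories: `B <= 0.3` small,
`0.3 < B < 0.8` moderate, `B >= 0.8` large. No multiple-testing
correction is applied across the 70 features — raw p values are reported
deliberately, matching the reporting convention the pipeline mirrors.

Numerical edge cases: noise-free tables make the mixed model singular, so
a perfect-fit detector falls back to the exact least-squares solution
(coefficients exact, p values 0/1 by whether a term is present);
constant features are flagged degenerate and excluded from family
summaries with a warning; `sigma_b = 0` flags `B` degenerate rather than
dividing by zero. Whether Wald-normal or t/Satterthwaite references were
used originally is unknown; the normal approximation is used here and at
n = 28 subjects its CI coverage is verified by simulation to sit in the
low-to-mid 90s.

## Problem sizes used in validation

The shipped validation uses desk-scale problems chosen to exercise every
code path: oracle equivalence on 100 random 2D arrays (up to 8x8, up to 6
grey levels) and 20 random 3D arrays (up to 4x6x6) against brute-force
enumerators shipped with the tests; fractal calibration on 256^2
fractional Brownian surfaces at H in {0.3, 0.5, 0.7}; effect-model
recovery on 200 simulated 28-subject cohorts plus 1000 null replicates
for the type-I rate of cubic-term retention; and the full demonstration
run on the default 28-subject phantom.

## Known limitations

* DICOM series ingestion is not implemented — volumes and masks are
  consumed as NIfTI (attenuation already in HU). Conversion from DICOM is
  left to standard external tools.
* 2D texture directions are strictly in-plane and the 3D mode treats the
  5-slice block as an isotropy-blind lattice (no distance weighting for
  the 5 mm slice axis); a config flag can exclude out-of-plane directions
  entirely.
* Texture features are invariant to *monotone level-preserving* maps
  only; arbitrary level relabelling changes most features, which is
  intrinsic to grey-level statistics and not asserted as an invariant.
* The GLRL/GLZSM "variability" feature names have no published formulas;
  the normalised non-uniformity reading is documented but remains an
  interpretation.
* Registration/resampling of mismatched grids, ROI drawing, wavelet and
  shape features, and volumetric fractal estimators are out of scope.
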