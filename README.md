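# asirtex

Quantifies how adaptive statistical iterative reconstruction (ASIR)
weightings alter CT radiomics features measured in tumour regions of
interest. CT scanners reconstruct the same acquisition at a chosen ASIR
percentage (0% = filtered back projection, 100% = maximal iterative
denoising); because most radiomics features are sensitive to image noise,
the reconstruction weighting alone shifts their values. `asirtex` is for
imaging scientists who need to measure that shift: it extracts 70
features from six-weight reconstruction series in single-slice (2D) and
multi-slice (3D) modes, and models each feature's response to weighting
with a two-level random-intercept regression.

## What it computes

**Features** (per subject, weight and mode):

| family | count | content |
|---|---|---|
| first-order | 10 | histogram statistics of the ROI (mean ... kurtosis, energy, entropy) |
| GLCM | 19 | grey-level co-occurrence (Haralick) features, distance 1, direction-averaged |
| GLDM | 4 | grey-level difference statistics (mean, entropy, variance, contrast) |
| NGTDM | 5 | neighbourhood grey-tone difference (Amadasun-King) features |
| GLRL | 13 | run-length features, direction-averaged |
| GLZSM | 13 | zone-size features over connected equal-level zones |
| fractal | 6 | box-counting fractal dimension (mean, SD), lacunarity, Hurst exponent, blanket mean/max (2D only) |

**Effect model**: for each feature, a two-level model with measurements
nested in subjects,

    y_ij = beta_0 + u_i + beta x_ij + (optional x^2, x^3 terms) + e_ij,
    x = weight / 20,   u_i ~ N(0, sigma_b^2),   e_ij ~ N(0, sigma_e^2),

fitted by REML. Cubic and squared terms are dropped sequentially when
non-significant (alpha = 0.05). The reported coefficient `beta` is the
change in the feature per 20% ASIR increment, with Wald 95% CI and p
value; the standardised effect size is `B = |beta| / sigma_b`
(small <= 0.3 < moderate < 0.8 <= large). Fractal lacunarity is analysed
on the log scale.

Because no patient images are distributed, the package ships a synthetic
phantom cohort generator (`phantom_params()`, `generate_cohort()`) that
emulates the essential structure: 28 subjects with tumour-like textured
ROIs, between-subject heterogeneity, and a per-weight noise level that
decreases progressively with ASIR weighting (a convex blend of one noisy
realisation with its smoothed copy). Five of the 28 tumours span fewer
than five slices and so contribute 2D analysis only, mirroring the
multi-slice exclusion rule.

## Worked example

```r
library(asirtex)

params  <- phantom_params(n_subjects = 6, seed = 42)
cohort  <- generate_cohort(params)
features <- run_extraction(default_config(), cohort = cohort)

head(features, 3)
#>   subject_id asir_weight         mode feature_name     value
#> 1 phantom_01           0 single_slice         mean  88.51988
#> 2 phantom_01           0 single_slice      maximum 134.16642
#> 3 phantom_01           0 single_slice      minimum  44.41574

sd_tab <- subset(features, mode == "single_slice" &
                           feature_name == "standard_deviation")
est <- fit_random_intercept(sd_tab, shape = select_shape(sd_tab))
est
#> <effect_estimate> quadratic: coef -1.016 (-1.094, -0.9379) per 20% ASIR,
#>   p = 1.35e-143, B = 1.28 (large)
```

Read: on this 6-subject phantom the ROI standard deviation falls by about
1.0 HU per 20% ASIR increment (95% CI -1.09 to -0.94) — the emulated
denoising at work — and the change is large relative to the 0.8 HU
between-subject spread (`B = 1.28`). On this synthetic cohort the
response curvature is detectable, so shape selection retains a quadratic
term; effect sizes on phantom data are intentionally not calibrated to
clinical magnitudes.

The full pipeline (extraction + effect models + report CSV files shaped
like per-feature summary tables) runs from a YAML config:

```r
run_full(system.file("extdata", "demo_config.yaml", package = "asirtex"),
         out_dir = "demo_out")
```

or from the shell via the thin CLI wrapper:

```sh
Rscript inst/cli/asirtex.R run --config inst/extdata/demo_config.yaml --out demo_out
```

Real data enter through a CSV manifest (one row per subject: `subject_id`,
`mask`, `w0` ... `w100` NIfTI paths); see `read_manifest()`. Volumes must
be grid-congruent across weights — mismatched subjects are excluded, not
resampled.

## Layout

- `R/` — implementation (imaging IO, preprocessing, feature families,
  fractal estimators, phantom generator, effect model, pipeline).
- `tests/testthat/` — unit and property tests, including brute-force
  oracle enumerators for every texture-matrix family and a
  criterion-per-block acceptance suite.
- `vignettes/asirtex-methods.Rmd` — the methods vignette: model
  assumptions, parameter choices, estimator design, limitations.
- `inst/extdata/demo_config.yaml` — the demonstration configuration.
- `inst/cli/asirtex.R` — command-line wrapper (`run`, `synth`,
  `extract`, `fit`).
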