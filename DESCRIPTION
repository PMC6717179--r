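Package: asirtex
Title: Effect of Iterative-Reconstruction Weighting on CT Radiomics Texture Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies how adaptive statistical iterative reconstruction (ASIR)
    weightings alter CT radiomics features measured in tumour regions of
    interest. Provides a 2D (single-slice) and 3D (multi-slice) extraction
    engine for 70 features spanning first-order histogram statistics,
    grey-level co-occurrence, difference, run-length, zone-size and
    neighbourhood grey-tone difference matrices, and model-based fractal
    measures of the intensity surface; a synthetic phantom cohort generator
    that emulates the progressive noise reduction of incremental ASIR
    weighting; and a two-level random-intercept regression procedure with
    polynomial shape selection and standardised effect sizes reporting the
    change per 20% ASIR increment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    lme4,
    igraph,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
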