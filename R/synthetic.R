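# Synthetic phantom cohorts with the statistical structure the analysis
# assumes: subject-level heterogeneity, tumour-like spatially correlated
# texture, and a per-series noise level that decreases smoothly with ASIR
# weight. The proprietary reconstruction algorithm itself is emulated, not
# implemented: the volume at weight w is a convex blend of one noisy
# realisation with a Gaussian-smoothed copy of itself,
# v_w = (1 - lambda(w)) * noisy + lambda(w) * smoothed(noisy),
# so all six weights share a single underlying realisation and differ only
# by reconstruction-like progressive smoothing.

.subject_seed <- function(seed, subject_index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(subject_index) * 10007) %%
               2147483629)
}

#' Parameters of the synthetic phantom cohort
#'
#' Defaults mirror the study cohort: 28 subjects, 5 of which have tumours
#' spanning fewer than 5 axial slices (and so contribute single-slice
#' analysis only). Attenuation is in HU; the tumour plateau sits on a
#' darker background, carries a spatially correlated texture field and
#' i.i.d. noise whose blended reduction across weights emulates the
#' progressive smoothing of incremental ASIR.
#'
#' @param n_subjects Number of subjects (default 28).
#' @param grid_shape `(slices, rows, cols)` of each volume.
#' @param spacing Voxel spacing in mm `(x, y, z)`.
#' @param roi_radius_range In-plane tumour radius range, voxels.
#' @param roi_slices_range Slice extent range for full-size tumours
#'   (>= 5 slices).
#' @param small_slices_range Slice extent range for the sub-5-slice tumours.
#' @param fraction_small Fraction of subjects whose tumour spans < 5 slices
#'   (default 5/28).
#' @param base_mean Mean tumour attenuation (HU) across subjects.
#' @param between_sd Between-subject SD of the tumour attenuation (HU).
#' @param contrast Tumour-to-background attenuation difference (HU).
#' @param rim_amplitude Amplitude (HU) of an optional radial enhancement
#'   profile (`base - rim_amplitude` at the core to `base + rim_amplitude`
#'   at the rim); 0 (default) gives a homogeneous plateau.
#' @param texture_sd SD of the correlated texture field (HU).
#' @param texture_corr_length In-plane Gaussian correlation length, voxels.
#' @param noise_sd SD of i.i.d. bounded-support (uniform) noise at weight 0
#'   (HU). Bounded support keeps the ROI intensity extremes, and so the
#'   per-weight discretisation range, a stable multiple of the noise SD.
#' @param emul_sigma Gaussian sigma (voxels) of the reconstruction-emulation
#'   smoothing.
#' @param lambda Blend schedule: function mapping weight (percent) to blend
#'   fraction in `[0, 1]`; must satisfy `lambda(0) = 0` and be
#'   non-decreasing. Default `0.85 * w / 100`: the highest weighting removes
#'   most but not all noise, keeping the emulated reduction strictly
#'   progressive across all six weights.
#' @param seed Integer seed governing every random draw.
#' @return A validated `phantom_params` list.
#' @export
phantom_params <- function(n_subjects = 28L,
                           grid_shape = c(10L, 80L, 80L),
                           spacing = c(1, 1, 5),
                           roi_radius_range = c(24, 28),
                           roi_slices_range = c(5L, 7L),
                           small_slices_range = c(2L, 4L),
                           fraction_small = 5 / 28,
                           base_mean = 80,
                           between_sd = 15,
                           contrast = 30,
                           rim_amplitude = 0,
                           texture_sd = 12,
                           texture_corr_length = 2,
                           noise_sd = 30,
                           emul_sigma = 1.5,
                           lambda = function(w) 0.85 * w / 100,
                           seed = 1L) {
  p <- list(n_subjects = as.integer(n_subjects), grid_shape = as.integer(grid_shape),
            spacing = spacing, roi_radius_range = roi_radius_range,
            roi_slices_range = as.integer(roi_slices_range),
            small_slices_range = as.integer(small_slices_range),
            fraction_small = fraction_small, base_mean = base_mean,
            between_sd = between_sd, contrast = contrast,
            rim_amplitude = rim_amplitude,
            texture_sd = texture_sd, texture_corr_length = texture_corr_length,
            noise_sd = noise_sd, emul_sigma = emul_sigma, lambda = lambda,
            seed = as.integer(seed))
  if (p$n_subjects < 2L) stop("`n_subjects` must be >= 2")
  if (any(c(p$between_sd, p$texture_sd, p$noise_sd) < 0))
    stop("all SDs must be >= 0")
  lw <- vapply(asir_weights(), p$lambda, numeric(1))
  if (abs(lw[1]) > 1e-12) stop("lambda(0) must be 0")
  if (any(diff(lw) < -1e-12)) stop("lambda must be non-decreasing in weight")
  if (any(lw < 0 | lw > 1)) stop("lambda must map into [0, 1]")
  if (2 * max(p$roi_radius_range) + 2 > min(p$grid_shape[2:3]))
    stop("ROI larger than the grid")
  if (max(p$roi_slices_range) > p$grid_shape[1])
    stop("ROI slice extent exceeds the grid")
  class(p) <- "phantom_params"
  p
}

# in-plane Gaussian smoothing of a 3D array, slice by slice
.smooth_inplane <- function(arr, sigma) {
  size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  w <- .gaussian_kernel2(size, sigma)
  for (z in seq_len(dim(arr)[1])) arr[z, , ] <- .filter2(arr[z, , ], w)
  arr
}

#' Generate one subject's six-weight series and tumour mask
#'
#' Deterministic given `(params$seed, subject_index)`. The tumour is an
#' ellipsoid (tapered in-plane radius across slices) whose plateau value is
#' drawn per subject; the texture field is Gaussian-smoothed white noise at
#' the configured correlation length; i.i.d. noise of `noise_sd` is added
#' once, and the six weights are convex blends of that single realisation
#' with its Gaussian-smoothed copy. Subjects designated "small" (the last
#' `round(fraction_small * n_subjects)` subject indices) span fewer than 5
#' slices and exercise the multi-slice exclusion rule.
#'
#' @param params A [phantom_params()].
#' @param subject_index Subject number in `1..n_subjects`.
#' @return List with `series` (a [recon_series()]) and `mask`
#'   (a [roi_mask()]).
#' @export
generate_subject_series <- function(params, subject_index) {
  stopifnot(inherits(params, "phantom_params"))
  i <- as.integer(subject_index)
  if (i < 1L || i > params$n_subjects) stop("subject_index out of range")
  set.seed(.subject_seed(params$seed, i))
  d <- params$grid_shape
  n_small <- round(params$fraction_small * params$n_subjects)
  is_small <- i > params$n_subjects - n_small
  nsl <- if (is_small) {
    sample(seq(params$small_slices_range[1], params$small_slices_range[2]), 1)
  } else {
    sample(seq(params$roi_slices_range[1], params$roi_slices_range[2]), 1)
  }
  r_xy <- stats::runif(1, params$roi_radius_range[1], params$roi_radius_range[2])
  z0 <- sample(seq(1L, d[1] - nsl + 1L), 1)
  ctr_r <- d[2] / 2 + stats::runif(1, -2, 2)
  ctr_c <- d[3] / 2 + stats::runif(1, -2, 2)
  msk <- array(FALSE, d)
  rr <- matrix(seq_len(d[2]), d[2], d[3])
  cc <- matrix(seq_len(d[3]), d[2], d[3], byrow = TRUE)
  mu_i <- params$base_mean + stats::rnorm(1, 0, params$between_sd)
  base <- array(mu_i - params$contrast, d)
  for (k in seq_len(nsl)) {
    rel <- (k - (nsl + 1) / 2) / ((nsl + 1) / 2)
    rk <- max(r_xy * sqrt(max(0, 1 - rel^2)), 1.5)
    rho2 <- ((rr - ctr_r)^2 + (cc - ctr_c)^2) / rk^2
    inside <- rho2 <= 1
    msk[z0 + k - 1L, , ] <- inside
    # rim-enhancing radial profile: hypodense core, enhancing rim
    sl <- base[z0 + k - 1L, , ]
    sl[inside] <- mu_i + params$rim_amplitude * (2 * rho2[inside] - 1)
    base[z0 + k - 1L, , ] <- sl
  }
  tex <- array(stats::rnorm(prod(d)), d)
  tex <- .smooth_inplane(tex, params$texture_corr_length)
  tex <- tex / stats::sd(tex) * params$texture_sd
  # bounded-support (uniform) noise: keeps the ROI extremes, and hence the
  # per-weight discretisation range, a stable multiple of the noise SD
  a <- params$noise_sd * sqrt(3)
  noise <- array(stats::runif(prod(d), -a, a), d)
  noisy <- base + tex + noise
  smoothed <- .smooth_inplane(noisy, params$emul_sigma)
  vols <- lapply(asir_weights(), function(w) {
    lam <- params$lambda(w)
    image_volume((1 - lam) * noisy + lam * smoothed,
                 spacing = params$spacing)
  })
  names(vols) <- as.character(asir_weights())
  list(series = recon_series(sprintf("phantom_%02d", i), vols),
       mask = roi_mask(msk, spacing = params$spacing))
}

#' Generate a full phantom cohort
#'
#' @param params A [phantom_params()].
#' @return List of per-subject lists (`series`, `mask`), length
#'   `n_subjects`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  lapply(seq_len(params$n_subjects),
         function(i) generate_subject_series(params, i))
}

#' Write a cohort to NIfTI files with an ingestion manifest
#'
#' Writes each subject's six volumes and mask as NIfTI files under `dir`
#' and a `manifest.csv` compatible with [read_manifest()].
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(subj) {
    sid <- subj$series$subject_id
    paths <- vapply(as.character(asir_weights()), function(w) {
      p <- file.path(dir, sprintf("%s_w%s.nii.gz", sid, w))
      write_volume(subj$series$volumes[[w]], p)
      basename(p)
    }, character(1))
    mp <- file.path(dir, sprintf("%s_mask.nii.gz", sid))
    write_volume(subj$mask, mp)
    c(subject_id = sid, mask = basename(mp),
      stats::setNames(paths, paste0("w", asir_weights())))
  })
  man <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Simulate a feature table from the two-level generative model
#'
#' Draws `y_ij = (mu + u_i) + beta * x + gamma2 * x^2 + gamma3 * x^3 +
#' e_ij` with `x = weight / 20`, random intercepts `u_i ~ N(0, sigma_b^2)`
#' and residuals `e_ij ~ N(0, sigma_e^2)`. Used to exercise the effect
#' model in isolation with known truth.
#'
#' @param n_subjects Number of subjects.
#' @param weights ASIR weights (percent), default the six study weights.
#' @param mu Intercept mean.
#' @param sigma_b Between-subject SD of the random intercept.
#' @param beta Linear slope per 20-percent ASIR increment.
#' @param gamma2,gamma3 Optional quadratic and cubic coefficients (in the
#'   same per-20 units).
#' @param sigma_e Residual SD.
#' @param seed Integer seed.
#' @param feature_name,mode Labels stamped on the output rows.
#' @return Long-format data frame with columns `subject_id`, `asir_weight`,
#'   `mode`, `feature_name`, `value`.
#' @export
simulate_feature_table <- function(n_subjects, weights = asir_weights(),
                                   mu = 0, sigma_b = 1, beta = 0,
                                   gamma2 = 0, gamma3 = 0, sigma_e = 1,
                                   seed = 1L, feature_name = "sim_feature",
                                   mode = "single_slice") {
  if (sigma_b < 0 || sigma_e < 0) stop("SDs must be >= 0")
  if (!all(weights %in% 0:100)) stop("weights must lie in 0..100")
  set.seed(as.integer(seed))
  u <- stats::rnorm(n_subjects, 0, sigma_b)
  out <- expand.grid(subject_id = sprintf("s%03d", seq_len(n_subjects)),
                     asir_weight = weights, stringsAsFactors = FALSE)
  x <- out$asir_weight / 20
  out$mode <- mode
  out$feature_name <- feature_name
  out$value <- mu + u[match(out$subject_id,
                            sprintf("s%03d", seq_len(n_subjects)))] +
    beta * x + gamma2 * x^2 + gamma3 * x^3 +
    stats::rnorm(nrow(out), 0, sigma_e)
  out
}

#' Synthetic fractional Brownian surface
#'
#' Spectral synthesis of a 2D fractional Brownian field with Hurst exponent
#' `H`: Fourier amplitudes follow a power law in the discrete frequency
#' response `2 sin(pi f)` (rather than `f` itself), which preserves the
#' `d^H` scaling of increments down to the pixel scale on a finite grid.
#' The surface is normalised to unit SD. Used as the known-roughness
#' calibration input for [fractal_dimension()].
#'
#' @param n Surface side length (pixels).
#' @param H Hurst exponent in `(0, 1)`.
#' @param seed Integer seed.
#' @return `n x n` numeric matrix.
#' @export
fbm_surface <- function(n, H, seed = 1L) {
  if (H <= 0 || H >= 1) stop("`H` must be in (0, 1)")
  set.seed(as.integer(seed))
  f <- (0:(n - 1)) / n
  s2 <- (2 * sin(pi * f))^2
  fsq <- outer(s2, s2, "+")
  amp <- ifelse(fsq == 0, 0, fsq^(-(H + 1) / 2))
  ph <- matrix(stats::rnorm(n * n), n, n) +
    1i * matrix(stats::rnorm(n * n), n, n)
  s <- Re(stats::fft(amp * ph, inverse = TRUE)) / n
  s / stats::sd(s)
}
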