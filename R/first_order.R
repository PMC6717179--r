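#' First-order (histogram) features
#'
#' The ten first-order features describe the distribution of voxel
#' intensities inside the ROI with no spatial information. Moment statistics
#' (mean, maximum, minimum, range, standard deviation, coefficient of
#' variation, skewness, kurtosis) are computed on the smoothed raw HU
#' values; energy and entropy are computed on the 32-level discretised
#' histogram probabilities. Conventions: SD uses the sample (n-1)
#' denominator; skewness and kurtosis use population moments
#' (`m3/m2^1.5`, `m4/m2^2`), kurtosis is reported non-excess (Gaussian
#' values are near 3); entropy is in bits, with `0 log 0 := 0`.
#'
#' Degenerate cases are returned as `NA`: coefficient of variation when the
#' mean is 0, skewness and kurtosis when the SD is 0.
#'
#' @param roi A `discretised_roi` (see [discretise()]).
#' @return Named numeric vector of 10 features.
#' @export
first_order_features <- function(roi) {
  stopifnot(inherits(roi, "discretised_roi"))
  v <- roi$raw[roi$mask]
  n <- length(v)
  if (n == 0L) stop("empty ROI")
  m <- mean(v)
  sdv <- if (n > 1L) stats::sd(v) else 0
  m2 <- mean((v - m)^2)
  skew <- if (m2 > 0) mean((v - m)^3) / m2^1.5 else NA_real_
  kurt <- if (m2 > 0) mean((v - m)^4) / m2^2 else NA_real_
  cv <- if (m != 0) sdv / m else NA_real_
  lev <- roi$levels[roi$mask]
  p <- tabulate(lev, nbins = roi$Ng) / n
  p <- p[p > 0]
  c(mean = m,
    maximum = max(v),
    minimum = min(v),
    range = max(v) - min(v),
    standard_deviation = sdv,
    coefficient_of_variation = cv,
    skewness = skew,
    kurtosis = kurt,
    energy = sum(p^2),
    entropy = -sum(p * log2(p)))
}
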