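#' Grey-level co-occurrence matrices of a discretised ROI
#'
#' One symmetric, normalised GLCM per displacement direction at voxel
#' distance `d`. Pairs are counted only when both voxels are inside the
#' mask; each directional count matrix is symmetrised by adding its
#' transpose and normalised to sum to 1.
#'
#' @param roi A `discretised_roi`.
#' @param d Voxel distance (default 1).
#' @return List of `Ng x Ng` probability matrices, one per direction.
#' @export
glcm_matrices <- function(roi, d = 1L) {
  stopifnot(inherits(roi, "discretised_roi"))
  dirs <- direction_set(.feature_mode(roi), d)
  Ng <- roi$Ng
  out <- vector("list", nrow(dirs))
  for (k in seq_len(nrow(dirs))) {
    pr <- .offset_pairs(roi$levels, dirs[k, ])
    if (!length(pr$a)) { out[[k]] <- NULL; next }
    counts <- matrix(tabulate(pr$a + Ng * (pr$b - 1L), nbins = Ng * Ng), Ng, Ng)
    counts <- counts + t(counts)
    out[[k]] <- counts / sum(counts)
  }
  out[!vapply(out, is.null, logical(1))]
}

# The 19 Haralick-style features of one normalised symmetric GLCM.
.glcm_feature_one <- function(P) {
  Ng <- nrow(P)
  i <- row(P); j <- col(P)
  pi_ <- rowSums(P)            # marginal (symmetric: px = py)
  mu <- sum(seq_len(Ng) * pi_)
  sig2 <- sum((seq_len(Ng) - mu)^2 * pi_)
  sig <- sqrt(sig2)
  # diagonal (difference) and cross (sum) distributions
  k_diff <- 0:(Ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  k_sum <- 2:(2 * Ng)
  p_sum <- vapply(k_sum, function(k) sum(P[(i + j) == k]), numeric(1))
  mu_diff <- sum(k_diff * p_diff)
  hxy <- .h2(P)
  hx <- .h2(pi_)
  # information measures need p(i)p(j) terms over cells with P > 0
  ppij <- outer(pi_, pi_)
  pos <- P > 0
  hxy1 <- -sum(P[pos] * log2(ppij[pos]))
  hxy2 <- .h2(ppij)
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else NA_real_
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * log(2) * (hxy2 - hxy))))
  corr <- if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else NA_real_
  c(glcm_autocorrelation = sum(i * j * P),
    glcm_cluster_prominence = sum((i + j - 2 * mu)^4 * P),
    glcm_cluster_shade = sum((i + j - 2 * mu)^3 * P),
    glcm_contrast = sum((i - j)^2 * P),
    glcm_correlation = corr,
    glcm_difference_entropy = .h2(p_diff),
    glcm_difference_variance = sum((k_diff - mu_diff)^2 * p_diff),
    glcm_dissimilarity = sum(abs(i - j) * P),
    glcm_entropy = hxy,
    glcm_energy = sum(P^2),
    glcm_homogeneity = sum(P / (1 + abs(i - j))),
    glcm_information_measure_correlation_1 = imc1,
    glcm_information_measure_correlation_2 = imc2,
    glcm_inverse_difference_moment_normalised = sum(P / (1 + (i - j)^2 / Ng^2)),
    glcm_inverse_difference_normalised = sum(P / (1 + abs(i - j) / Ng)),
    glcm_maximum_probability = max(P),
    glcm_sum_average = sum(k_sum * p_sum),
    glcm_sum_entropy = .h2(p_sum),
    glcm_sum_of_squares_variance = sum((i - mu)^2 * P))
}

#' Grey-level co-occurrence (GLCM) features
#'
#' Computes the 19 Haralick-style GLCM features from symmetric normalised
#' co-occurrence matrices at voxel distance `d` (4 in-plane directions in
#' single-slice mode, 13 volumetric directions in multi-slice mode) and
#' reports the mean over directions. Entropies are base 2. Correlation is
#' `NA` (degenerate) when the marginal variance is zero, and the information
#' measure of correlation 1 is `NA` when the marginal entropy is zero.
#'
#' @param roi A `discretised_roi`.
#' @param d Voxel distance (default 1).
#' @return Named numeric vector of 19 features.
#' @export
glcm_features <- function(roi, d = 1L) {
  mats <- glcm_matrices(roi, d)
  if (!length(mats))
    stop("no valid in-mask voxel pairs at distance ", d)
  per_dir <- vapply(mats, .glcm_feature_one, numeric(19L))
  rowMeans(per_dir)
}
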