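#' Grey-level difference (GLDM) features
#'
#' The grey-level difference matrix records the distribution of absolute
#' grey-level differences `k = |i - j|` over all in-mask voxel pairs at
#' distance `d`. One difference histogram is built per displacement
#' direction (the same direction set as the GLCM) and the four features
#' (mean, entropy, variance, contrast) are averaged over directions, so
#' that, by construction, GLDM mean equals GLCM dissimilarity and GLDM
#' contrast equals GLCM contrast on every input.
#'
#' @param roi A `discretised_roi`.
#' @param d Voxel distance (default 1).
#' @return Named numeric vector: `gldm_mean`, `gldm_entropy`,
#'   `gldm_variance`, `gldm_contrast`.
#' @export
gldm_features <- function(roi, d = 1L) {
  stopifnot(inherits(roi, "discretised_roi"))
  dirs <- direction_set(.feature_mode(roi), d)
  Ng <- roi$Ng
  per_dir <- NULL
  for (k in seq_len(nrow(dirs))) {
    pr <- .offset_pairs(roi$levels, dirs[k, ])
    if (!length(pr$a)) next
    diffs <- abs(pr$a - pr$b)
    p <- tabulate(diffs + 1L, nbins = Ng) / length(diffs)
    kk <- 0:(Ng - 1)
    mu <- sum(kk * p)
    f <- c(gldm_mean = mu,
           gldm_entropy = .h2(p),
           gldm_variance = sum((kk - mu)^2 * p),
           gldm_contrast = sum(kk^2 * p))
    per_dir <- cbind(per_dir, f)
  }
  if (is.null(per_dir)) stop("no valid in-mask voxel pairs at distance ", d)
  rowMeans(per_dir)
}
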