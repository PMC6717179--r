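#' Neighbourhood grey-tone difference (NGTDM) features
#'
#' For each in-mask voxel with at least one in-mask neighbour
#' (8-neighbourhood in-plane for single-slice mode, 26-neighbourhood for
#' multi-slice mode), the absolute difference between its level and the
#' mean level of its in-mask neighbours is accumulated per grey level
#' (`s_k`). The five Amadasun-King features (coarseness, contrast,
#' busyness, complexity, texture strength) are computed from the occupancy
#' probabilities `p_k` and the `s_k`. Coarseness is guarded as
#' `1/(1e-6 + sum(p_k s_k))` so a perfectly uniform region returns the
#' capped value `1e6` rather than infinity.
#'
#' @param roi A `discretised_roi`.
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(roi) {
  stopifnot(inherits(roi, "discretised_roi"))
  eps <- 1e-6
  lev <- roi$levels
  offs <- .neighbour_offsets(.feature_mode(roi))
  d <- dim(lev)
  nb_sum <- array(0, d)
  nb_cnt <- array(0L, d)
  for (k in seq_len(nrow(offs))) {
    sh <- .shift_array(lev, offs[k, ])
    ok <- !is.na(sh)
    nb_sum[ok] <- nb_sum[ok] + sh[ok]
    nb_cnt[ok] <- nb_cnt[ok] + 1L
  }
  contrib <- roi$mask & nb_cnt > 0L
  if (!any(contrib)) stop("no in-mask voxel has an in-mask neighbour")
  li <- lev[contrib]
  dev <- abs(li - nb_sum[contrib] / nb_cnt[contrib])
  Ng <- roi$Ng
  n_k <- tabulate(li, nbins = Ng)
  s_k <- vapply(seq_len(Ng), function(g) sum(dev[li == g]), numeric(1))
  N <- sum(n_k)
  p_k <- n_k / N
  occ <- which(p_k > 0)
  Ngp <- length(occ)
  ps <- sum(p_k * s_k)
  coarseness <- 1 / (eps + ps)
  if (Ngp > 1) {
    ii <- occ[rep(seq_along(occ), each = length(occ))]
    jj <- occ[rep(seq_along(occ), times = length(occ))]
    contrast <- sum(p_k[ii] * p_k[jj] * (ii - jj)^2) / (Ngp * (Ngp - 1)) *
      sum(s_k) / N
    denom_busy <- sum(abs(ii * p_k[ii] - jj * p_k[jj])[ii != jj])
    busyness <- if (denom_busy > 0) ps / denom_busy else 0
    off_diag <- ii != jj
    complexity <- sum((abs(ii - jj) *
                         (p_k[ii] * s_k[ii] + p_k[jj] * s_k[jj]) /
                         (p_k[ii] + p_k[jj]))[off_diag]) / N
    strength <- sum(((p_k[ii] + p_k[jj]) * (ii - jj)^2)[off_diag]) /
      (eps + sum(s_k))
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(ngtdm_coarseness = coarseness,
    ngtdm_contrast = contrast,
    ngtdm_busyness = busyness,
    ngtdm_complexity = complexity,
    ngtdm_texture_strength = strength)
}
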