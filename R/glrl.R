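# Run-length matrix for one direction: maximal runs of equal level along
# in-mask collinear voxel sequences; off-mask voxels break runs.
.glrl_matrix_one <- function(lev, off) {
  d <- dim(lev)
  z <- slice.index(lev, 1); r <- slice.index(lev, 2); c_ <- slice.index(lev, 3)
  back <- function(coord, o, n) {
    if (o == 0L) rep(.Machine$integer.max, length(coord))
    else if (o > 0L) coord - 1L
    else n - coord
  }
  k <- pmin(back(z, off[1], d[1]), back(r, off[2], d[2]), back(c_, off[3], d[3]))
  base_z <- z - k * off[1]; base_r <- r - k * off[2]; base_c <- c_ - k * off[3]
  lineid <- (base_z - 1) + d[1] * ((base_r - 1) + d[2] * (base_c - 1))
  ord <- order(lineid, k)
  lv <- as.integer(lev)[ord]
  lid <- lineid[ord]
  n <- length(lv)
  prev <- c(NA_integer_, lv[-n])
  same_line <- c(FALSE, lid[-1] == lid[-n])
  same <- same_line & !is.na(lv) & !is.na(prev) & lv == prev
  runstart <- !is.na(lv) & !same
  rid <- cumsum(runstart)
  in_mask <- !is.na(lv)
  run_len <- tabulate(rid[in_mask])
  run_lev <- lv[runstart]
  list(g = run_lev, l = run_len)
}

# The 13 run-length features from runs (g = level, l = length) of one
# direction. "Intensity variability" and "run length variability" are the
# normalised grey-level / run-length non-uniformities.
.glrl_feature_one <- function(g, l, Np) {
  Nr <- length(g)
  sum_g <- tapply(rep(1, Nr), g, sum)           # runs per level
  sum_l <- tapply(rep(1, Nr), l, sum)           # runs per length
  c(glrl_run_percentage = Nr / Np,
    glrl_high_grey_level_run_emphasis = sum(g^2) / Nr,
    glrl_short_run_low_grey_level_emphasis = sum(1 / (g^2 * l^2)) / Nr,
    glrl_short_run_high_grey_level_emphasis = sum(g^2 / l^2) / Nr,
    glrl_short_run_emphasis = sum(1 / l^2) / Nr,
    glrl_long_run_emphasis = sum(l^2) / Nr,
    glrl_grey_level_non_uniformity = sum(sum_g^2) / Nr,
    glrl_run_length_non_uniformity = sum(sum_l^2) / Nr,
    glrl_low_grey_level_run_emphasis = sum(1 / g^2) / Nr,
    glrl_long_run_low_grey_level_emphasis = sum(l^2 / g^2) / Nr,
    glrl_long_run_high_grey_level_emphasis = sum(l^2 * g^2) / Nr,
    glrl_intensity_variability = sum(sum_g^2) / Nr^2,
    glrl_run_length_variability = sum(sum_l^2) / Nr^2)
}

#' Grey-level run-length (GLRL) features
#'
#' Runs are maximal sequences of collinear in-mask voxels sharing one grey
#' level; off-mask voxels break runs. One run-length matrix `R(g, l)` is
#' built per direction (4 in-plane directions in single-slice mode, 13 in
#' multi-slice mode) and the 13 features are averaged over directions.
#' "Intensity variability" and "run length variability" are implemented as
#' the normalised grey-level and run-length non-uniformities (an
#' interpretation of non-standard feature names; see the package vignette).
#'
#' @param roi A `discretised_roi`.
#' @return Named numeric vector of 13 features.
#' @export
glrl_features <- function(roi) {
  stopifnot(inherits(roi, "discretised_roi"))
  Np <- sum(roi$mask)
  if (Np == 0L) stop("empty ROI")
  dirs <- direction_set(.feature_mode(roi), 1L)
  per_dir <- vapply(seq_len(nrow(dirs)), function(k) {
    runs <- .glrl_matrix_one(roi$levels, dirs[k, ])
    .glrl_feature_one(runs$g, runs$l, Np)
  }, numeric(13L))
  rowMeans(per_dir)
}
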