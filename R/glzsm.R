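#' Grey-level zone-size (GLZSM) features
#'
#' Zones are connected components of equal grey level within the mask
#' (8-connectivity in-plane for single-slice mode, 26-connectivity for
#' multi-slice mode). A single zone-count matrix `Z(g, s)` (level by zone
#' size) is built per ROI and the 13 features are computed from it.
#' "Intensity variability" and "size zone variability" are the normalised
#' intensity / zone-length non-uniformities (see the package vignette for
#' the naming interpretation).
#'
#' @param roi A `discretised_roi`.
#' @return Named numeric vector of 13 features.
#' @export
glzsm_features <- function(roi) {
  stopifnot(inherits(roi, "discretised_roi"))
  zones <- .glzsm_zones(roi)
  g <- zones$g; s <- zones$s
  Np <- sum(roi$mask)
  Nz <- length(g)
  sum_g <- tapply(rep(1, Nz), g, sum)   # zones per level
  sum_s <- tapply(rep(1, Nz), s, sum)   # zones per size
  c(glzsm_short_zone_emphasis = sum(1 / s^2) / Nz,
    glzsm_short_zone_low_intensity_emphasis = sum(1 / (s^2 * g^2)) / Nz,
    glzsm_short_zone_high_intensity_emphasis = sum(g^2 / s^2) / Nz,
    glzsm_long_zone_low_intensity_emphasis = sum(s^2 / g^2) / Nz,
    glzsm_long_zone_high_intensity_emphasis = sum(s^2 * g^2) / Nz,
    glzsm_long_zone_emphasis = sum(s^2) / Nz,
    glzsm_intensity_non_uniformity = sum(sum_g^2) / Nz,
    glzsm_zone_length_non_uniformity = sum(sum_s^2) / Nz,
    glzsm_zone_percentage = Nz / Np,
    glzsm_low_intensity_zone_emphasis = sum(1 / g^2) / Nz,
    glzsm_high_intensity_zone_emphasis = sum(g^2) / Nz,
    glzsm_intensity_variability = sum(sum_g^2) / Nz^2,
    glzsm_size_zone_variability = sum(sum_s^2) / Nz^2)
}

# Connected components of equal level within the mask; returns the level g
# and size s of every zone.
.glzsm_zones <- function(roi) {
  lev <- roi$levels
  idx <- which(!is.na(lev))
  if (!length(idx)) stop("empty ROI")
  vid <- integer(length(lev))
  vid[idx] <- seq_along(idx)
  dim(vid) <- dim(lev)
  half <- direction_set(.feature_mode(roi), 1L)
  edges <- NULL
  for (k in seq_len(nrow(half))) {
    off <- half[k, ]
    sh <- .shift_array(lev, off)          # sh[v] = level at v - off
    shid <- .shift_int(vid, off, dim(lev))
    ok <- !is.na(lev) & !is.na(sh) & lev == sh
    if (any(ok)) edges <- rbind(edges, cbind(vid[ok], shid[ok]))
  }
  if (is.null(edges)) {
    memb <- seq_along(idx)                # all isolated voxels
  } else {
    gph <- igraph::graph_from_edgelist(edges, directed = FALSE)
    gph <- igraph::add_vertices(gph, max(0L, length(idx) - igraph::vcount(gph)))
    memb <- igraph::components(gph)$membership[seq_along(idx)]
  }
  s <- as.vector(table(memb))
  first <- match(sort(unique(memb)), memb)
  g <- as.integer(lev[idx][first])
  list(g = g, s = s)
}

# integer-array variant of .shift_array (0 fill)
.shift_int <- function(arr, off, d) {
  out <- array(0L, dim = d)
  rng <- function(n, o) {
    if (abs(o) >= n) return(list(dst = integer(0), src = integer(0)))
    if (o >= 0) list(dst = seq_len(n - o), src = seq_len(n - o) + o)
    else list(dst = seq(1L - o, n), src = seq_len(n + o))
  }
  r1 <- rng(d[1], off[1]); r2 <- rng(d[2], off[2]); r3 <- rng(d[3], off[3])
  if (!length(r1$dst) || !length(r2$dst) || !length(r3$dst)) return(out)
  out[r1$dst, r2$dst, r3$dst] <- arr[r1$src, r2$src, r3$src]
  out
}
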