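# Shared machinery for the grey-level matrix families. All builders obey the
# masked-edge rule: a pair / neighbour / run step exists only when both
# voxels lie inside the mask (NA levels break everything).

#' Displacement direction set for a texture mode
#'
#' Single-slice (2D) analysis uses the 4 unique in-plane unit directions;
#' multi-slice (3D) analysis uses the 13 unique directions of the
#' 26-neighbourhood (one of each +/- pair). Offsets are `(slice, row,
#' column)` voxel steps scaled by the distance `d`.
#'
#' @param mode `"single_slice"` or `"multi_slice"`.
#' @param d Integer voxel distance (default 1).
#' @return Integer matrix, one direction per row.
#' @export
direction_set <- function(mode = c("single_slice", "multi_slice"), d = 1L) {
  mode <- match.arg(mode)
  if (mode == "single_slice") {
    m <- rbind(c(0L, 0L, 1L), c(0L, 1L, 0L), c(0L, 1L, 1L), c(0L, 1L, -1L))
  } else {
    g <- as.matrix(expand.grid(dz = -1:1, dr = -1:1, dc = -1:1))
    g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), , drop = FALSE]
    keep <- g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) |
      (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0)
    m <- g[keep, , drop = FALSE]
    colnames(m) <- NULL
  }
  m * as.integer(d)
}

# Full (both signs) neighbourhood offsets: 8 in-plane or 26 volumetric.
.neighbour_offsets <- function(mode) {
  half <- direction_set(mode, 1L)
  rbind(half, -half)
}

# Extract the level values of all valid voxel pairs at `off`. Returns
# list(a, b) of equal-length integer vectors (may be empty).
.offset_pairs <- function(arr, off) {
  d <- dim(arr)
  rng <- function(n, o) {
    if (abs(o) >= n) return(integer(0))
    if (o >= 0) seq_len(n - o) else seq(1L - o, n)
  }
  i1 <- rng(d[1], off[1]); j1 <- rng(d[2], off[2]); k1 <- rng(d[3], off[3])
  if (!length(i1) || !length(j1) || !length(k1))
    return(list(a = integer(0), b = integer(0)))
  a <- arr[i1, j1, k1, drop = FALSE]
  b <- arr[i1 + off[1], j1 + off[2], k1 + off[3], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  list(a = as.integer(a[ok]), b = as.integer(b[ok]))
}

# Shift an array by `off`, filling exposed borders with NA.
.shift_array <- function(arr, off) {
  d <- dim(arr)
  out <- array(NA_integer_, dim = d)
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

# entropy-style sum with the 0 log 0 := 0 convention, base 2
.h2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

.feature_mode <- function(roi) {
  if (roi$mode == "single_slice") "single_slice" else "multi_slice"
}
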