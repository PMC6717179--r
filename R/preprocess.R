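# In-plane 2D filtering with replicated edges. Kernels are small (3-7 px),
# so filtering is done as a sum of shifted padded copies.

.pad_replicate <- function(m, k) {
  ri <- c(rep(1L, k), seq_len(nrow(m)), rep(nrow(m), k))
  ci <- c(rep(1L, k), seq_len(ncol(m)), rep(ncol(m), k))
  m[ri, ci, drop = FALSE]
}

.filter2 <- function(m, w) {
  # w: (2k+1) x (2k+1) kernel, sums to 1
  k <- (nrow(w) - 1L) %/% 2L
  p <- .pad_replicate(m, k)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(w))) for (j in seq_len(ncol(w))) {
    if (w[i, j] == 0) next
    out <- out + w[i, j] * p[(i - 1L) + seq_len(nrow(m)),
                             (j - 1L) + seq_len(ncol(m)), drop = FALSE]
  }
  out
}

.median_filter2 <- function(m, size) {
  k <- (size - 1L) %/% 2L
  p <- .pad_replicate(m, k)
  stack <- array(NA_real_, c(nrow(m), ncol(m), size * size))
  s <- 0L
  for (i in seq_len(size)) for (j in seq_len(size)) {
    s <- s + 1L
    stack[, , s] <- p[(i - 1L) + seq_len(nrow(m)),
                      (j - 1L) + seq_len(ncol(m)), drop = FALSE]
  }
  apply(stack, c(1, 2), stats::median)
}

.gaussian_kernel2 <- function(size, sigma) {
  k <- (size - 1L) %/% 2L
  x <- -k:k
  g <- exp(-x^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

#' Pre-extraction smoothing filter
#'
#' Applies the "medium" smoothing step that precedes grey-level
#' discretisation: an in-plane (per-axial-slice) filter with replicated
#' edges. The default is a 3x3 mean filter; Gaussian and median variants are
#' selectable. `size = 1` is the identity. Grid metadata is unchanged.
#'
#' @param volume An [image_volume()].
#' @param size Odd kernel size in pixels (default 3).
#' @param kind One of `"mean"`, `"gaussian"`, `"median"`.
#' @param sigma Gaussian standard deviation in pixels (defaults to `size/3`).
#' @return A smoothed [image_volume()].
#' @export
smooth_volume <- function(volume, size = 3L, kind = c("mean", "gaussian", "median"),
                          sigma = size / 3) {
  stopifnot(inherits(volume, "image_volume"))
  kind <- match.arg(kind)
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L) stop("`size` must be odd and >= 1")
  if (size == 1L) return(volume)
  vox <- volume$voxels
  w <- switch(kind,
              mean = matrix(1 / size^2, size, size),
              gaussian = .gaussian_kernel2(size, sigma),
              median = NULL)
  for (z in seq_len(dim(vox)[1])) {
    sl <- vox[z, , ]
    vox[z, , ] <- if (kind == "median") .median_filter2(sl, size)
                  else .filter2(sl, w)
  }
  image_volume(vox, spacing = volume$spacing, origin = volume$origin)
}

# Map values to integer levels 1..Ng. Returns list(levels, edges).
.discretise_values <- function(v, Ng, method = "fixed_count", bin_width = 32) {
  if (any(!is.finite(v))) stop("non-finite voxel values inside the mask")
  lo <- min(v); hi <- max(v)
  if (method == "fixed_count") {
    if (hi == lo) {
      lev <- rep(1L, length(v))
      edges <- lo + c(0, 1)
    } else {
      lev <- 1L + as.integer(floor(Ng * (v - lo) / (hi - lo)))
      lev <- pmin.int(pmax.int(lev, 1L), Ng)
      edges <- seq(lo, hi, length.out = Ng + 1L)
    }
  } else if (method == "fixed_width") {
    lev <- 1L + as.integer(floor((v - lo) / bin_width))
    nb <- max(lev)
    if (nb > Ng) stop(sprintf(
      "fixed-width binning needs %d levels but Ng = %d; raise Ng or bin_width",
      nb, Ng))
    edges <- lo + bin_width * (0:Ng)
  } else stop("unknown discretisation method: ", method)
  list(levels = lev, edges = edges)
}

#' Grey-level discretisation of an analysis region
#'
#' Maps the masked voxels of an analysis region to integer grey levels
#' `1..Ng`. The default ("fixed_count") uses `Ng` equal-width bins over the
#' region's own intensity range: `level = 1 + floor(Ng * (v - min)/(max -
#' min))` clipped to `[1, Ng]`; a constant region maps entirely to level 1.
#' The min/max are recomputed per region and per reconstruction. A
#' fixed-bin-width alternative (`method = "fixed_width"`, width in HU) is
#' provided for sensitivity analyses.
#'
#' @param region An `analysis_region` from [select_regions()].
#' @param volume The (smoothed) [image_volume()] at one ASIR weight.
#' @param Ng Number of grey levels (default 32).
#' @param method `"fixed_count"` (default) or `"fixed_width"`.
#' @param bin_width Bin width in HU, used only for `"fixed_width"`.
#' @return An object of class `discretised_roi` with fields `levels`
#'   (integer array, `NA` off-mask), `raw` (smoothed HU, `NA` off-mask),
#'   `mask`, `Ng`, `bin_edges`, `mode`, `spacing`.
#' @export
discretise <- function(region, volume, Ng = 32L, method = c("fixed_count", "fixed_width"),
                       bin_width = 32) {
  stopifnot(inherits(region, "analysis_region"), inherits(volume, "image_volume"))
  method <- match.arg(method)
  Ng <- as.integer(Ng)
  if (Ng < 2L) stop("`Ng` must be >= 2")
  sub <- volume$voxels[region$slices, , , drop = FALSE]
  if (!identical(dim(sub), dim(region$mask)))
    stop("region mask and volume grids are incompatible")
  msk <- region$mask
  if (!any(msk)) stop("region mask is empty")
  vals <- sub[msk]
  dz <- .discretise_values(vals, Ng, method, bin_width)
  levels <- array(NA_integer_, dim = dim(msk))
  levels[msk] <- dz$levels
  raw <- array(NA_real_, dim = dim(msk))
  raw[msk] <- vals
  structure(list(levels = levels, raw = raw, mask = msk, Ng = Ng,
                 bin_edges = dz$edges, mode = region$mode,
                 spacing = region$spacing),
            class = "discretised_roi")
}

#' @export
print.discretised_roi <- function(x, ...) {
  cat(sprintf("<discretised_roi> %s, %d voxels, Ng = %d (%d levels occupied)\n",
              x$mode, sum(x$mask), x$Ng, length(unique(x$levels[x$mask]))))
  invisible(x)
}

#' Build a discretised ROI directly from a level array
#'
#' Wraps an already-binned integer level array (with `NA` marking off-mask
#' voxels) as a `discretised_roi`, so texture features can be computed on
#' pre-binned data. A 2D matrix is treated as a single axial slice.
#'
#' @param levels Integer array of grey levels in `1..Ng`, `NA` off-mask;
#'   2D `(row, column)` or 3D `(slice, row, column)`.
#' @param Ng Number of grey levels.
#' @param mode `"single_slice"` or `"multi_slice"`; decides in-plane vs
#'   volumetric neighbourhoods downstream.
#' @param raw Optional array of raw values congruent with `levels`; defaults
#'   to the levels themselves.
#' @param spacing Voxel spacing (mm), metadata only.
#' @return A `discretised_roi`.
#' @export
as_discretised_roi <- function(levels, Ng, mode = c("single_slice", "multi_slice"),
                               raw = NULL, spacing = c(1, 1, 1)) {
  mode <- match.arg(mode)
  if (!length(levels)) stop("`levels` is empty")
  lv <- levels[!is.na(levels)]
  if (!length(lv)) stop("`levels` has no in-mask voxels")
  if (any(lv < 1 | lv > Ng | lv != round(lv)))
    stop("`levels` must be integers in 1..Ng on the mask")
  if (!is.null(raw) && length(dim(raw)) == 2L) dim(raw) <- c(1L, dim(raw))
  .droi_from_levels(levels, Ng, mode, raw, spacing)
}

.droi_from_levels <- function(levels, Ng, mode, raw = NULL, spacing = c(1, 1, 1)) {
  if (is.null(dim(levels))) dim(levels) <- c(1L, 1L, length(levels))
  if (length(dim(levels)) == 2L) dim(levels) <- c(1L, dim(levels))
  levels <- array(as.integer(levels), dim = dim(levels))
  mask <- !is.na(levels)
  if (is.null(raw)) raw <- array(as.numeric(levels), dim = dim(levels))
  structure(list(levels = levels, raw = raw, mask = mask, Ng = as.integer(Ng),
                 bin_edges = seq(0.5, Ng + 0.5, by = 1), mode = mode,
                 spacing = spacing),
            class = "discretised_roi")
}
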