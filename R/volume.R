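#' ASIR weights of a reconstruction series
#'
#' The six adaptive statistical iterative reconstruction (ASIR) percentage
#' weightings at which each CT acquisition is reconstructed. 0% corresponds to
#' pure filtered back projection.
#'
#' @return Integer vector `c(0, 20, 40, 60, 80, 100)`.
#' @export
asir_weights <- function() c(0L, 20L, 40L, 60L, 80L, 100L)

# grid congruence tolerances (mm); any mismatch beyond these excludes a series
.SPACING_TOL <- 1e-6
.ORIGIN_TOL <- 1e-3

#' Construct an image volume
#'
#' A 3D grid of CT attenuation values (Hounsfield units) with spacing and
#' origin metadata. The array axis convention is `(slice, row, column)`:
#' axial slices are indexed along the first axis.
#'
#' @param voxels Numeric 3D array of attenuation values (HU), axes
#'   `(slice, row, column)`.
#' @param spacing Numeric length-3 vector, voxel spacing in mm as
#'   `(x, y, z)` = (column, row, slice) pitch. All components must be > 0.
#' @param origin Numeric length-3 vector, position of the first voxel in mm.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array (slice, row, column)")
  if (length(voxels) == 0L) stop("`voxels` must be non-empty")
  if (!all(is.finite(voxels))) stop("`voxels` contains non-finite values")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite values (mm)")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %d slices x %d x %d, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Construct a binary region-of-interest mask
#'
#' A binary tumour mask on the same grid as its companion [image_volume()].
#' Fractional (partial-volume) masks are rejected: every voxel must be
#' exactly 0/1 (or logical).
#'
#' @param voxels Logical or 0/1 numeric 3D array, axes `(slice, row, column)`.
#' @param spacing,origin Grid metadata, as for [image_volume()].
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("mask `voxels` must be a 3D array (slice, row, column)")
  if (is.numeric(voxels)) {
    if (!all(voxels %in% c(0, 1)))
      stop("mask must be binary (0/1); fractional masks are not supported")
    storage <- array(voxels == 1, dim = dim(voxels))
  } else if (is.logical(voxels)) {
    storage <- voxels
  } else stop("mask `voxels` must be logical or 0/1 numeric")
  if (!any(storage)) stop("mask has no foreground voxels")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three positive values (mm)")
  structure(list(voxels = storage, spacing = spacing, origin = origin),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s, %d foreground voxels\n",
              paste(dim(x$voxels), collapse = "x"), sum(x$voxels)))
  invisible(x)
}

#' Bundle the six ASIR reconstructions of one subject
#'
#' @param subject_id Character scalar label.
#' @param volumes Named list of six [image_volume()] objects; names must be
#'   the ASIR weights `"0", "20", ..., "100"` (order irrelevant).
#' @return An object of class `recon_series`.
#' @export
recon_series <- function(subject_id, volumes) {
  want <- as.character(asir_weights())
  if (!is.list(volumes) || is.null(names(volumes)) ||
      !setequal(names(volumes), want) || length(volumes) != 6L)
    stop("`volumes` must be a named list with exactly the weights ",
         paste(want, collapse = ", "))
  ok <- vapply(volumes, inherits, logical(1), what = "image_volume")
  if (!all(ok)) stop("all elements of `volumes` must be image_volume objects")
  structure(list(subject_id = as.character(subject_id),
                 volumes = volumes[want]),
            class = "recon_series")
}

.grid_of <- function(x) list(shape = dim(x$voxels), spacing = x$spacing,
                             origin = x$origin)

#' Verify grid congruence across a reconstruction series
#'
#' All six reconstructions of a subject must live on an identical grid:
#' identical array shape, spacing within 1e-6 mm and origin within 1e-3 mm of
#' the 0% (filtered back projection) series. A spatial mismatch between the
#' 0% series and any re-weighted series excludes the subject from analysis,
#' so any violation is an error naming the offending weight and attribute.
#'
#' @param series A [recon_series()].
#' @return Invisibly `TRUE` on success; otherwise an error.
#' @export
assert_series_congruent <- function(series) {
  stopifnot(inherits(series, "recon_series"))
  ref <- .grid_of(series$volumes[["0"]])
  for (w in as.character(asir_weights())) {
    g <- .grid_of(series$volumes[[w]])
    if (!identical(g$shape, ref$shape))
      stop(sprintf("series '%s': volume at weight %s%% mismatches on shape (%s vs %s)",
                   series$subject_id, w, paste(g$shape, collapse = "x"),
                   paste(ref$shape, collapse = "x")))
    if (any(abs(g$spacing - ref$spacing) > .SPACING_TOL))
      stop(sprintf("series '%s': volume at weight %s%% mismatches on spacing",
                   series$subject_id, w))
    if (any(abs(g$origin - ref$origin) > .ORIGIN_TOL))
      stop(sprintf("series '%s': volume at weight %s%% mismatches on origin",
                   series$subject_id, w))
  }
  invisible(TRUE)
}

#' Copy a 0%-ASIR ROI onto every reconstruction of the series
#'
#' The tumour ROI is drawn once on the 0% (FBP) series and copied unchanged
#' onto the 20--100% reconstructions, guaranteeing voxel-identical ROIs at
#' every weight. Requires the series to be grid-congruent and the mask to
#' share the 0% volume's grid.
#'
#' @param mask A [roi_mask()] drawn on the 0% volume.
#' @param series A [recon_series()].
#' @return Named list (one entry per weight) of identical [roi_mask()]s.
#' @export
propagate_roi <- function(mask, series) {
  stopifnot(inherits(mask, "roi_mask"))
  assert_series_congruent(series)
  ref <- .grid_of(series$volumes[["0"]])
  if (!identical(dim(mask$voxels), ref$shape) ||
      any(abs(mask$spacing - ref$spacing) > .SPACING_TOL) ||
      any(abs(mask$origin - ref$origin) > .ORIGIN_TOL))
    stop("mask grid does not match the 0% volume grid")
  out <- lapply(as.character(asir_weights()), function(w) mask)
  names(out) <- as.character(asir_weights())
  out
}

#' Derive single-slice (2D) and multi-slice (3D) analysis regions
#'
#' The single-slice region is the axial slice holding the largest tumour
#' area (most masked voxels; ties broken towards the lowest slice index).
#' The multi-slice region is the contiguous 5-slice window, every slice of
#' which contains tumour, that maximises the total masked voxel count (ties
#' to the lowest start index). When no 5 contiguous slices all contain
#' tumour the multi-slice region is absent (`NULL`), mirroring the exclusion
#' of tumours too small for segmentation on five consecutive axial slices.
#'
#' @param mask A [roi_mask()].
#' @return List with elements `single` and `multi` (each an
#'   `analysis_region` or `NULL` for `multi`).
#' @export
select_regions <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  counts <- apply(mask$voxels, 1, sum)
  if (all(counts == 0)) stop("mask has no foreground voxels")
  s <- which.max(counts)  # which.max returns the first (lowest) maximum
  single <- .analysis_region(mask, slices = s, mode = "single_slice")
  nz <- length(counts)
  multi <- NULL
  if (nz >= 5L) {
    starts <- seq_len(nz - 4L)
    valid <- vapply(starts, function(a) all(counts[a:(a + 4L)] > 0), logical(1))
    if (any(valid)) {
      tot <- vapply(starts, function(a) sum(counts[a:(a + 4L)]), numeric(1))
      tot[!valid] <- -Inf
      a <- which.max(tot)
      multi <- .analysis_region(mask, slices = a:(a + 4L), mode = "multi_slice")
    }
  }
  list(single = single, multi = multi)
}

.analysis_region <- function(mask, slices, mode) {
  sub <- mask$voxels[slices, , , drop = FALSE]
  structure(list(mode = mode, slices = as.integer(slices), mask = sub,
                 spacing = mask$spacing, origin = mask$origin),
            class = "analysis_region")
}

#' @export
print.analysis_region <- function(x, ...) {
  cat(sprintf("<analysis_region> %s, slices %s, %d masked voxels\n",
              x$mode, paste(range(x$slices), collapse = "-"), sum(x$mask)))
  invisible(x)
}

# ---- NIfTI input/output -----------------------------------------------------

#' Read a volume from a NIfTI file
#'
#' Reads a `.nii`/`.nii.gz` file into an [image_volume()], reordering axes to
#' the package's `(slice, row, column)` convention. Values are taken as
#' already scaled to Hounsfield units (RNifti applies any scl slope and
#' intercept on read).
#'
#' @param path Path to a NIfTI file.
#' @return An [image_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI volume: ", path)
  hdr <- RNifti::niftiHeader(img)
  sp <- abs(RNifti::pixdim(img))[1:3]
  orig <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
  image_volume(aperm(arr, c(3, 2, 1)), spacing = sp, origin = orig)
}

#' Write a volume (or mask) to a NIfTI file
#'
#' @param vol An [image_volume()] or [roi_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, c("image_volume", "roi_mask")))
  arr <- vol$voxels
  if (is.logical(arr)) arr <- array(as.numeric(arr), dim = dim(arr))
  arr <- aperm(arr, c(3, 2, 1))  # back to NIfTI (x, y, z)
  attr(arr, "pixdim") <- vol$spacing
  img <- RNifti::asNifti(arr, datatype = "double")
  xf <- diag(4)
  diag(xf)[1:3] <- vol$spacing
  xf[1:3, 4] <- vol$origin
  img <- RNifti::`qform<-`(img, structure(xf, code = 1L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary ROI mask from a NIfTI file
#'
#' Voxels must be exactly 0 or 1 (after any on-read scaling); fractional
#' masks are rejected.
#'
#' @param path Path to a NIfTI file.
#' @return A [roi_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  vox <- v$voxels
  if (!all(abs(vox) < 1e-9 | abs(vox - 1) < 1e-9))
    stop("mask file is not binary (0/1): ", path)
  roi_mask(array(vox > 0.5, dim = dim(vox)), spacing = v$spacing,
           origin = v$origin)
}

#' Read a cohort ingestion manifest
#'
#' One row per subject: a `subject_id` column, a `mask` column (NIfTI path)
#' and six volume path columns `w0, w20, w40, w60, w80, w100`. Relative
#' paths are resolved against the manifest's directory.
#'
#' @param path Path to a CSV manifest.
#' @return Data frame with resolved paths.
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "mask", paste0("w", asir_weights()))
  miss <- setdiff(need, names(man))
  if (length(miss)) stop("manifest is missing columns: ",
                         paste(miss, collapse = ", "))
  base <- dirname(normalizePath(path))
  for (col in setdiff(need, "subject_id")) {
    rel <- !grepl("^(/|[A-Za-z]:)", man[[col]])
    man[[col]][rel] <- file.path(base, man[[col]][rel])
  }
  man
}

#' Load one subject's series and mask from manifest paths
#'
#' @param row One row of a [read_manifest()] data frame.
#' @return List with elements `series` ([recon_series()]) and `mask`
#'   ([roi_mask()]).
#' @export
load_subject <- function(row) {
  vols <- lapply(as.character(asir_weights()),
                 function(w) read_volume(row[[paste0("w", w)]]))
  names(vols) <- as.character(asir_weights())
  list(series = recon_series(row$subject_id, vols),
       mask = read_mask(row$mask))
}
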