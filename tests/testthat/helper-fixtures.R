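# Fixture builders shared across the suite. Everything is generated in
# code; no binary fixtures are stored.

# random masked level array wrapped as a discretised ROI
rand_droi <- function(seed, dims, Ng, mode = NULL, p_mask = 0.75) {
  set.seed(seed)
  if (is.null(mode)) mode <- if (length(dims) == 2L || dims[1] == 1L)
    "single_slice" else "multi_slice"
  if (length(dims) == 2L) dims <- c(1L, dims)
  repeat {
    lev <- array(sample.int(Ng, prod(dims), replace = TRUE), dim = dims)
    msk <- array(stats::runif(prod(dims)) < p_mask, dim = dims)
    lev[!msk] <- NA_integer_
    # need >= 2 voxels, >= 2 levels, and at least one in-mask pair somewhere
    if (sum(msk) >= 4L && length(unique(lev[msk])) >= 2L) break
  }
  as_discretised_roi(lev, Ng = Ng, mode = mode)
}

rand_volume <- function(seed, dims = c(3L, 8L, 8L), spacing = c(1, 1, 5),
                        origin = c(0, 0, 0)) {
  set.seed(seed)
  image_volume(array(stats::rnorm(prod(dims), 50, 20), dim = dims),
               spacing = spacing, origin = origin)
}

# ellipsoid-ish mask on given slices
disc_mask <- function(dims, slices, radius, ctr = NULL,
                      spacing = c(1, 1, 5)) {
  if (is.null(ctr)) ctr <- c(dims[2] / 2, dims[3] / 2)
  m <- array(FALSE, dims)
  rr <- matrix(seq_len(dims[2]), dims[2], dims[3])
  cc <- matrix(seq_len(dims[3]), dims[2], dims[3], byrow = TRUE)
  for (z in slices) m[z, , ] <- (rr - ctr[1])^2 + (cc - ctr[2])^2 <= radius^2
  roi_mask(m, spacing = spacing)
}

# six-volume congruent series around one base volume
series_from <- function(base, subject_id = "s1") {
  vols <- lapply(asir_weights(), function(w) base)
  names(vols) <- as.character(asir_weights())
  recon_series(subject_id, vols)
}

# small phantom parameters for fast pipeline tests (fractal still viable:
# lacunarity's largest default box is 16, needing radius >= 12)
test_phantom_params <- function(n_subjects = 4L, seed = 7L, ...) {
  phantom_params(n_subjects = n_subjects,
                 grid_shape = c(10L, 40L, 40L),
                 roi_radius_range = c(12, 14),
                 fraction_small = if (n_subjects >= 4) 1 / n_subjects else 0,
                 seed = seed, ...)
}
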