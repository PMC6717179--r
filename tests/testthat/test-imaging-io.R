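test_that("NIfTI round trip preserves voxels, spacing and origin", {
  vol <- rand_volume(11, dims = c(4L, 7L, 9L), spacing = c(0.98, 0.98, 5),
                     origin = c(-120.5, -88, 33.25))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume(f)
  expect_equal(back$voxels, vol$voxels, tolerance = 1e-12)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  expect_equal(back$origin, vol$origin, tolerance = 1e-4)
  # a second round trip is bit-stable
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(back, f2)
  expect_identical(read_volume(f2)$voxels, back$voxels)
})

test_that("mask IO is binary-safe", {
  msk <- disc_mask(c(3L, 10L, 10L), slices = 2, radius = 3)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(msk, f)
  back <- read_mask(f)
  expect_identical(back$voxels, msk$voxels)
  # fractional values are rejected
  bad <- rand_volume(2, dims = c(2L, 4L, 4L))
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(bad, f2)
  expect_error(read_mask(f2), "binary")
  expect_error(roi_mask(array(0.5, c(1, 2, 2))), "binary")
})

test_that("volume and mask constructors enforce their invariants", {
  expect_error(image_volume(array(1, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "spacing")
  expect_error(image_volume(array(c(1, NA), c(1, 1, 2))), "finite")
  expect_error(image_volume(matrix(1, 2, 2)), "3D")
  expect_error(roi_mask(array(FALSE, c(2, 2, 2))), "foreground")
})

test_that("series congruence passes identical grids and names the offender", {
  base <- rand_volume(3, dims = c(3L, 6L, 6L))
  series <- series_from(base)
  expect_true(assert_series_congruent(series))

  shifted <- image_volume(base$voxels, spacing = base$spacing,
                          origin = base$origin + c(1, 0, 0))
  vols <- series$volumes; vols[["60"]] <- shifted
  expect_error(assert_series_congruent(recon_series("s1", vols)),
               "60%.*origin")

  extra <- image_volume(base$voxels[c(1:3, 3), , , drop = FALSE],
                        spacing = base$spacing, origin = base$origin)
  vols <- series$volumes; vols[["40"]] <- extra
  expect_error(assert_series_congruent(recon_series("s1", vols)),
               "40%.*shape")
})

test_that("ROI propagation returns six voxel-identical copies", {
  base <- rand_volume(4, dims = c(4L, 12L, 12L))
  series <- series_from(base)
  msk <- disc_mask(c(4L, 12L, 12L), slices = 2:3, radius = 3)
  copies <- propagate_roi(msk, series)
  expect_named(copies, as.character(asir_weights()))
  for (w in names(copies)) {
    expect_identical(copies[[w]]$voxels, msk$voxels)
    expect_identical(sum(copies[[w]]$voxels), sum(msk$voxels))
  }
  # idempotence: propagating a propagated mask changes nothing
  again <- propagate_roi(copies[["100"]], series)
  expect_identical(again[["0"]]$voxels, msk$voxels)
})

test_that("region selection follows the largest-area and best-window rules", {
  # slices 2..7 hold 3, 10, 8, 8, 8, 8 masked voxels
  counts <- c(0, 3, 10, 8, 8, 8, 8, 0)
  m <- array(FALSE, c(8L, 4L, 4L))
  for (z in seq_along(counts)) if (counts[z] > 0)
    m[z, , ][seq_len(counts[z])] <- TRUE
  regions <- select_regions(roi_mask(m))
  expect_identical(regions$single$slices, 3L)
  expect_identical(regions$multi$slices, 3:7)
  expect_identical(sum(regions$multi$mask), 42L)

  # single-slice-only mask: multi absent
  m1 <- disc_mask(c(6L, 8L, 8L), slices = 4, radius = 2)
  r1 <- select_regions(m1)
  expect_identical(r1$single$slices, 4L)
  expect_null(r1$multi)

  # exactly five contiguous slices: the only candidate window
  m5 <- disc_mask(c(8L, 8L, 8L), slices = 3:7, radius = 2)
  expect_identical(select_regions(m5)$multi$slices, 3:7)
})

test_that("best 5-slice window beats every window in an exhaustive scan", {
  for (seed in 1:8) {
    set.seed(seed)
    nz <- 9L
    counts <- sample(0:12, nz, replace = TRUE)
    if (all(counts == 0)) counts[5] <- 3
    m <- array(FALSE, c(nz, 5L, 5L))
    for (z in seq_len(nz)) if (counts[z] > 0) m[z, , ][seq_len(counts[z])] <- TRUE
    regions <- select_regions(roi_mask(m))
    expect_identical(regions$single$slices, which.max(counts))
    starts <- seq_len(nz - 4L)
    ok <- vapply(starts, function(a) all(counts[a:(a + 4)] > 0), logical(1))
    if (!any(ok)) {
      expect_null(regions$multi)
    } else {
      best <- max(vapply(starts[ok], function(a) sum(counts[a:(a + 4)]),
                         numeric(1)))
      expect_identical(sum(regions$multi$mask), as.integer(best))
    }
  }
})

test_that("manifest round trip loads a subject", {
  dir <- withr::local_tempdir()
  params <- test_phantom_params(n_subjects = 2L, seed = 5L)
  cohort <- lapply(1:2, function(i) generate_subject_series(params, i))
  man_path <- write_cohort(cohort, dir)
  man <- read_manifest(man_path)
  expect_identical(nrow(man), 2L)
  subj <- load_subject(man[1, ])
  expect_true(assert_series_congruent(subj$series))
  expect_identical(subj$mask$voxels, cohort[[1]]$mask$voxels)
  expect_equal(subj$series$volumes[["40"]]$voxels,
               cohort[[1]]$series$volumes[["40"]]$voxels, tolerance = 1e-12)
})
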