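test_that("a flat surface has fractal dimension 2 and zero spread", {
  flat <- matrix(5, 24, 24)
  fd <- fractal_dimension(flat)
  expect_equal(fd$fd_mean, 2, tolerance = 1e-12)
  expect_equal(fd$fd_sd, 0, tolerance = 1e-12)
})

test_that("fd estimates always lie in [2, 3] and track surface roughness", {
  rough <- fbm_surface(64, 0.3, seed = 5)
  smooth <- fbm_surface(64, 0.7, seed = 5)
  fd_r <- fractal_dimension(rough)
  fd_s <- fractal_dimension(smooth)
  ok <- fd_r$fd_map[!is.na(fd_r$fd_map)]
  expect_true(all(ok >= 2 & ok <= 3))
  expect_gt(fd_r$fd_mean, fd_s$fd_mean)
})

test_that("fd decreases as smoothing of a fixed noisy surface increases", {
  fd_by_smoothing <- vapply(c(1L, 3L, 5L), function(k) {
    means <- vapply(1:5, function(seed) {
      set.seed(seed + 600)
      vol <- image_volume(array(rnorm(48 * 48, 0, 10), c(1L, 48L, 48L)))
      sm <- smooth_volume(vol, k)
      fractal_dimension(sm$voxels[1, , ])$fd_mean
    }, numeric(1))
    mean(means)
  }, numeric(1))
  expect_true(all(diff(fd_by_smoothing) < 0))
})

test_that("lacunarity is exactly 1 for constant mass and n for one spike", {
  const <- matrix(3L, 12, 12)
  for (r in c(2L, 3L, 4L))
    expect_equal(lacunarity(const, box_sizes = r), 1, tolerance = 1e-12)

  spike <- matrix(0L, 5, 5); spike[2, 3] <- 1L
  expect_equal(lacunarity(spike, box_sizes = 1L), 25, tolerance = 1e-12)
})

test_that("lacunarity matches the brute-force gliding-box oracle", {
  for (seed in 1:4) {
    set.seed(seed + 80)
    lev <- matrix(sample.int(6L, 100, replace = TRUE), 10, 10)
    lev[sample(100, 15)] <- NA_integer_  # irregular mask
    got <- lacunarity(lev, box_sizes = c(2L, 3L))
    expect_equal(got, o_lacunarity(lev, c(2L, 3L)), tolerance = 1e-12)
    expect_gte(got, 1)
  }
})

test_that("the Hurst exponent is the FD complement", {
  expect_equal(hurst_exponent(2.5), 0.5)
  expect_equal(hurst_exponent(2.0), 1.0)
  expect_equal(hurst_exponent(3.0), 0.0)
  expect_error(hurst_exponent(1.9), "2, 3")
})

test_that("blanket features: flat-surface area, shift invariance, ordering", {
  flat <- matrix(12, 9, 7)
  b <- blanket_features(flat, max_eps = 6L)
  expect_equal(unname(b["blanket_mean"]), 63, tolerance = 1e-12)
  expect_equal(unname(b["blanket_max"]), 63, tolerance = 1e-12)

  surf <- fbm_surface(32, 0.5, seed = 9) * 10
  b1 <- blanket_features(surf)
  b2 <- blanket_features(surf + 137.5)
  expect_equal(b1, b2, tolerance = 1e-10)
  expect_gte(unname(b1["blanket_max"]), unname(b1["blanket_mean"]))
})

test_that("blanket area is non-increasing in scale on fBm surfaces", {
  surf <- fbm_surface(48, 0.5, seed = 4) * 20
  u <- surf; b <- surf
  nbr_max <- function(m) {
    p <- asirtex:::.pad_replicate(m, 1L)
    n <- nrow(m); c_ <- ncol(m)
    pmax(m, p[1:n, 2:(c_ + 1)], p[3:(n + 2), 2:(c_ + 1)],
         p[2:(n + 1), 1:c_], p[2:(n + 1), 3:(c_ + 2)])
  }
  A <- numeric(6)
  for (eps in 1:6) {
    u <- pmax(u + 1, nbr_max(u)); b <- pmin(b - 1, -nbr_max(-b))
    A[eps] <- sum(u - b) / (2 * eps)
  }
  expect_true(all(diff(A) <= 1e-9))
})

test_that("the full fractal vector is computed on a single-slice region", {
  params <- test_phantom_params(n_subjects = 2L, seed = 3L)
  subj <- generate_subject_series(params, 1L)
  vol <- smooth_volume(subj$series$volumes[["40"]], 3)
  region <- select_regions(subj$mask)$single
  f <- fractal_features(region, vol)
  expect_named(f, c("fractal_dimension_mean", "fractal_dimension_sd",
                    "fractal_lacunarity", "hurst_exponent",
                    "blanket_mean", "blanket_max"))
  expect_true(all(is.finite(f)))
  expect_equal(unname(f["hurst_exponent"]),
               3 - unname(f["fractal_dimension_mean"]), tolerance = 1e-12)
  expect_gte(unname(f["fractal_lacunarity"]), 1)
})
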