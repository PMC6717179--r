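# Unit and property tests for the five grey-level matrix families. The
# exhaustive random-versus-oracle sweep lives in test-acceptance.R; here a
# smaller sample plus all hand-computable examples.

test_that("GLCM on an alternating row matches the hand enumeration", {
  droi <- as_discretised_roi(matrix(c(1L, 2L, 1L, 2L), 1, 4), Ng = 2L)
  f <- glcm_features(droi)
  # only the horizontal direction has pairs: 3 pairs, all (1,2)/(2,1)
  expect_equal(unname(f["glcm_contrast"]), 1)
  expect_equal(unname(f["glcm_homogeneity"]), 0.5)
  expect_equal(unname(f["glcm_maximum_probability"]), 0.5)
  expect_equal(unname(f["glcm_dissimilarity"]), 1)
  g <- gldm_features(droi)
  expect_equal(unname(g["gldm_mean"]), 1)
  expect_equal(unname(g["gldm_contrast"]), 1)
  expect_equal(unname(g["gldm_entropy"]), 0)
})

test_that("constant regions give the single-cell matrix identities", {
  droi <- as_discretised_roi(array(1L, c(1L, 4L, 4L)), Ng = 32L)
  f <- glcm_features(droi)
  expect_equal(unname(f["glcm_contrast"]), 0)
  expect_equal(unname(f["glcm_dissimilarity"]), 0)
  expect_equal(unname(f["glcm_homogeneity"]), 1)
  expect_equal(unname(f["glcm_energy"]), 1)
  expect_equal(unname(f["glcm_entropy"]), 0)
  expect_equal(unname(f["glcm_maximum_probability"]), 1)
  expect_true(is.na(f["glcm_correlation"]))
  g <- gldm_features(droi)
  expect_equal(unname(g), c(0, 0, 0, 0))
  n <- ngtdm_features(droi)
  expect_equal(unname(n["ngtdm_coarseness"]), 1e6)
  expect_equal(unname(n["ngtdm_contrast"]), 0)
  expect_equal(unname(n["ngtdm_busyness"]), 0)
})

test_that("single-direction run identities hold", {
  # single horizontal run of 4 equal voxels
  lev <- array(1L, c(1L, 1L, 4L))
  runs <- asirtex:::.glrl_matrix_one(lev, c(0L, 0L, 1L))
  f <- asirtex:::.glrl_feature_one(runs$g, runs$l, Np = 4L)
  expect_equal(unname(f["glrl_run_percentage"]), 0.25)
  expect_equal(unname(f["glrl_short_run_emphasis"]), 1 / 16)
  expect_equal(unname(f["glrl_long_run_emphasis"]), 16)

  # all-distinct row: four unit runs in every direction
  droi <- as_discretised_roi(matrix(1:4, 1, 4), Ng = 4L)
  f2 <- glrl_features(droi)
  expect_equal(unname(f2["glrl_run_percentage"]), 1)
  expect_equal(unname(f2["glrl_short_run_emphasis"]), 1)
  expect_equal(unname(f2["glrl_long_run_emphasis"]), 1)
})

test_that("zone identities: constant region and checkerboard", {
  droi <- as_discretised_roi(array(2L, c(1L, 4L, 4L)), Ng = 4L)
  f <- glzsm_features(droi)
  expect_equal(unname(f["glzsm_zone_percentage"]), 1 / 16)
  expect_equal(unname(f["glzsm_long_zone_emphasis"]), 256)

  # 4x4 checkerboard: under 8-connectivity the two colours form 2 zones of 8
  chk <- matrix(rep(c(1L, 2L), 8), 4, 4)
  chk[, c(2, 4)] <- 3L - chk[, c(2, 4)]
  f2 <- glzsm_features(as_discretised_roi(chk, Ng = 2L))
  expect_equal(unname(f2["glzsm_zone_percentage"]), 2 / 16)
})

test_that("NGTDM agrees with hand-computed neighbourhood sums on a 3x3", {
  # uniform level 1 plus one discrepant centre voxel of level 3
  lev <- matrix(1L, 3, 3); lev[2, 2] <- 3L
  f <- ngtdm_features(as_discretised_roi(lev, Ng = 3L))
  # centre: |3 - 1| = 2; each border voxel sees the centre in its
  # neighbourhood: corners mean (1*2 + 3)/3, edges mean (1*4 + 3)/5
  s1 <- 4 * abs(1 - 5 / 3) + 4 * abs(1 - 7 / 5)
  s3 <- 2
  n1 <- 8; n3 <- 1; N <- 9
  p1 <- n1 / N; p3 <- n3 / N
  coarse <- 1 / (1e-6 + p1 * s1 + p3 * s3)
  contr <- (p1 * p3 * 4 * 2) / (2 * 1) * (s1 + s3) / N
  expect_equal(unname(f["ngtdm_coarseness"]), coarse, tolerance = 1e-12)
  expect_equal(unname(f["ngtdm_contrast"]), contr, tolerance = 1e-12)
  busy <- (p1 * s1 + p3 * s3) / (2 * abs(1 * p1 - 3 * p3))
  expect_equal(unname(f["ngtdm_busyness"]), busy, tolerance = 1e-12)
})

test_that("every family matches its brute-force oracle on random inputs", {
  tol <- 1e-10
  for (seed in 1:6) {
    droi <- rand_droi(seed, c(6L, 6L), Ng = 4L)
    expect_equal(glcm_features(droi), o_glcm(droi), tolerance = tol)
    expect_equal(gldm_features(droi), o_gldm(droi), tolerance = tol)
    expect_equal(ngtdm_features(droi), o_ngtdm(droi), tolerance = tol)
    expect_equal(glrl_features(droi), o_glrl(droi), tolerance = tol)
    expect_equal(glzsm_features(droi), o_glzsm(droi), tolerance = tol)
  }
  for (seed in 1:3) {
    droi <- rand_droi(seed + 100, c(3L, 5L, 5L), Ng = 4L,
                      mode = "multi_slice")
    expect_equal(glcm_features(droi), o_glcm(droi), tolerance = tol)
    expect_equal(gldm_features(droi), o_gldm(droi), tolerance = tol)
    expect_equal(ngtdm_features(droi), o_ngtdm(droi), tolerance = tol)
    expect_equal(glrl_features(droi), o_glrl(droi), tolerance = tol)
    expect_equal(glzsm_features(droi), o_glzsm(droi), tolerance = tol)
  }
})

test_that("GLCM matrices are symmetric probability distributions", {
  for (seed in 1:5) {
    droi <- rand_droi(seed + 20, c(7L, 7L), Ng = 5L)
    for (P in glcm_matrices(droi)) {
      expect_equal(sum(P), 1, tolerance = 1e-12)
      expect_equal(P, t(P), tolerance = 1e-12)
    }
    f <- glcm_features(droi)
    for (nm in c("glcm_homogeneity", "glcm_energy", "glcm_maximum_probability")) {
      expect_gte(unname(f[nm]), 0)
      expect_lte(unname(f[nm]), 1)
    }
  }
})

test_that("run and zone masses conserve the voxel count", {
  for (seed in 1:5) {
    droi <- rand_droi(seed + 40, c(2L, 6L, 6L), Ng = 3L, mode = "multi_slice")
    Np <- sum(droi$mask)
    for (k in seq_len(nrow(direction_set("multi_slice")))) {
      runs <- asirtex:::.glrl_matrix_one(droi$levels,
                                         direction_set("multi_slice")[k, ])
      expect_identical(sum(runs$l), Np)
    }
    zones <- asirtex:::.glzsm_zones(droi)
    expect_identical(sum(zones$s), Np)
  }
})

test_that("direction sets have the stated cardinality and no negations", {
  d2 <- direction_set("single_slice")
  d3 <- direction_set("multi_slice")
  expect_identical(nrow(d2), 4L)
  expect_identical(nrow(d3), 13L)
  for (m in list(d2, d3)) {
    keys <- apply(m, 1, paste, collapse = ",")
    neg <- apply(-m, 1, paste, collapse = ",")
    expect_length(intersect(keys, neg), 0)
  }
})
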