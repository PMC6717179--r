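test_that("a noiseless linear table is recovered exactly", {
  tab <- simulate_feature_table(6, mu = 50, sigma_b = 0, beta = -1.27,
                                sigma_e = 0, seed = 1)
  expect_identical(select_shape(tab), "linear")
  est <- fit_random_intercept(tab, "linear")
  expect_equal(est$coef, -1.27, tolerance = 1e-10)
  expect_lt(est$p_value, 1e-10)
})

test_that("a strong quadratic generator is detected as quadratic", {
  hits <- vapply(1:10, function(r) {
    tab <- simulate_feature_table(28, mu = 0, sigma_b = 1, beta = 1,
                                  gamma2 = 10, sigma_e = 1, seed = 100 + r)
    select_shape(tab) == "quadratic"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("coefficients and B are recovered on noisy cohorts", {
  res <- vapply(1:25, function(r) {
    tab <- simulate_feature_table(28, mu = 100, sigma_b = 7, beta = -1.27,
                                  sigma_e = 1, seed = 200 + r)
    est <- fit_random_intercept(tab, "linear")
    c(est$coef, est$B, est$ci_low <= -1.27 && -1.27 <= est$ci_high)
  }, numeric(3))
  expect_equal(mean(res[1, ]), -1.27, tolerance = 0.05)
  expect_equal(mean(res[2, ]), 1.27 / 7, tolerance = 0.02)
  expect_gte(mean(res[3, ]), 0.8)
})

test_that("the standardised effect size is the absolute coefficient ratio", {
  expect_equal(standardised_effect(-0.5, 1.0), 0.5)
  expect_equal(standardised_effect(0, 2), 0)
  expect_true(is.na(standardised_effect(1, 0)))
})

test_that("effect categories partition [0, Inf) at 0.3 and 0.8", {
  expect_identical(classify_effect(0.3), "small")
  expect_identical(classify_effect(0.8), "large")
  expect_identical(classify_effect(0.49), "moderate")
  expect_identical(classify_effect(0), "small")
  # no gaps or overlaps across a fine grid
  grid <- seq(0, 2, by = 0.001)
  cats <- vapply(grid, classify_effect, character(1))
  expect_identical(sort(unique(cats)), c("large", "moderate", "small"))
  expect_true(all(diff(match(cats, c("small", "moderate", "large"))) >= 0))
  expect_error(classify_effect(-0.1), ">= 0")
})

test_that("B is invariant under positive rescaling of the feature", {
  tab <- simulate_feature_table(20, mu = 10, sigma_b = 2, beta = 0.8,
                                sigma_e = 0.5, seed = 31)
  est1 <- fit_random_intercept(tab, "linear")
  tab$value <- tab$value * 37.5
  est2 <- fit_random_intercept(tab, "linear")
  expect_equal(est1$B, est2$B, tolerance = 1e-6)
})

test_that("log-scale analysis requires positive values and transforms", {
  tab <- simulate_feature_table(10, mu = 2, sigma_b = 0.1, beta = 0.09,
                                sigma_e = 0.05, seed = 41)
  tab$value <- exp(tab$value)  # log-normal-ish, strictly positive
  est <- fit_random_intercept(tab, "linear", log_scale = TRUE)
  expect_lt(abs(est$coef - 0.09), 0.02)
  tab$value[1] <- -1
  expect_error(fit_random_intercept(tab, "linear", log_scale = TRUE),
               "positive")
})

test_that("feature families map as reported", {
  expect_identical(feature_family(c("mean", "entropy")),
                   c("first_order", "first_order"))
  expect_identical(feature_family("glcm_contrast"), "second_order")
  expect_identical(feature_family("gldm_mean"), "second_order")
  expect_identical(feature_family("glrl_run_percentage"), "high_order")
  expect_identical(feature_family("fractal_lacunarity"), "fractal")
})

test_that("summaries compute family medians/ranges and flag degenerates", {
  tabs <- do.call(rbind, lapply(seq_along(c(0.1, 0.3, 0.5)), function(i) {
    b <- c(0.1, 0.3, 0.5)[i]
    t <- simulate_feature_table(15, mu = 5, sigma_b = 1, beta = b,
                                sigma_e = 0.05, seed = 50 + i,
                                feature_name = c("glcm_contrast",
                                                 "glcm_entropy",
                                                 "glcm_energy")[i])
    t
  }))
  const <- simulate_feature_table(15, mu = 1, sigma_b = 0, beta = 0,
                                  sigma_e = 0, seed = 1,
                                  feature_name = "glcm_homogeneity")
  est <- fit_feature_effects(rbind(tabs, const))
  expect_identical(est$shape[est$feature_name == "glcm_homogeneity"],
                   "degenerate")
  expect_warning(s <- summarise_effects(est), "degenerate")
  fs <- s$family_summary
  expect_identical(fs$n_features, 3L)
  got_B <- sort(est$B[!is.na(est$B)])
  expect_equal(fs$median_B, got_B[2], tolerance = 1e-12)
  expect_equal(fs$min_B, got_B[1], tolerance = 1e-12)
  expect_equal(fs$max_B, got_B[3], tolerance = 1e-12)
  # and with clean inputs the median/range arithmetic is the plain one
  expect_equal(median(got_B), fs$median_B)
})
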