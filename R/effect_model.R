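# Two-level (random-intercept) regression of each radiomics feature on ASIR
# weight. Weight is coded x = weight/20 so the linear coefficient is
# directly the change per 20% ASIR increment. Estimation is by REML
# (lme4); coefficient tests and confidence intervals use the Wald normal
# approximation. Polynomial shape selection drops the cubic, then the
# quadratic term when non-significant at alpha = 0.05.

.FIRST_ORDER_NAMES <- c("mean", "maximum", "minimum", "range",
                        "standard_deviation", "coefficient_of_variation",
                        "skewness", "kurtosis", "energy", "entropy")
.FRACTAL_NAMES <- c("fractal_dimension_mean", "fractal_dimension_sd",
                    "fractal_lacunarity", "hurst_exponent",
                    "blanket_mean", "blanket_max")

#' Feature family of a feature name
#'
#' Maps a feature name to its reporting family: `first_order`,
#' `second_order` (GLCM + GLDM), `high_order` (NGTDM + GLRL + GLZSM) or
#' `fractal`.
#'
#' @param feature_name Character vector of feature names.
#' @return Character vector of family labels.
#' @export
feature_family <- function(feature_name) {
  out <- rep(NA_character_, length(feature_name))
  out[feature_name %in% .FIRST_ORDER_NAMES] <- "first_order"
  out[grepl("^(glcm|gldm)_", feature_name)] <- "second_order"
  out[grepl("^(ngtdm|glrl|glzsm)_", feature_name)] <- "high_order"
  out[feature_name %in% .FRACTAL_NAMES] <- "fractal"
  out
}

# Robust two-level fit of y on a polynomial in x with a per-subject random
# intercept. Returns the fixed-effect table and variance components.
.fit_two_level <- function(df, shape, log_scale = FALSE) {
  y <- df$value
  if (log_scale) {
    if (any(y <= 0)) stop("log-scale analysis requires strictly positive values")
    y <- log(y)
  }
  x <- df$asir_weight / 20
  subj <- factor(df$subject_id)
  if (nlevels(subj) < 2L) stop("need at least 2 subjects")
  terms <- c("x", "I(x^2)", "I(x^3)")[seq_len(shape)]
  dat <- data.frame(y = y, x = x, subj = subj)
  rhs <- paste(terms, collapse = " + ")
  scale_y <- max(stats::sd(y), 1e-12)
  # perfect (noise-free) fit: the mixed model is singular; fall back to the
  # exact least-squares solution
  ols <- stats::lm(stats::as.formula(paste("y ~", rhs, "+ subj")), data = dat)
  if (stats::sigma(ols) < 1e-8 * scale_y) {
    fx <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = dat)
    est <- stats::coef(fx)[terms]
    est[is.na(est)] <- 0
    subj_eff <- tapply(stats::resid(fx), dat$subj, mean)
    se <- rep(0, length(est))
    p <- ifelse(abs(est) > 1e-10 * scale_y, 0, 1)
    return(list(estimate = est, se = se, p = p,
                sigma_b = stats::sd(subj_eff), sigma_e = 0,
                degenerate = FALSE, engine = "exact"))
  }
  fml <- stats::as.formula(paste("y ~", rhs, "+ (1 | subj)"))
  fit <- tryCatch(
    suppressMessages(lme4::lmer(
      fml, data = dat, REML = TRUE,
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore"))),
    error = function(e) NULL)
  if (is.null(fit)) {
    # singular or failed mixed fit: per-subject fixed intercepts
    sm <- summary(ols)$coefficients
    est <- sm[terms, "Estimate"]
    se <- sm[terms, "Std. Error"]
    subj_eff <- stats::coef(ols)[grep("^subj", names(stats::coef(ols)))]
    return(list(estimate = est, se = se,
                p = 2 * stats::pnorm(-abs(est / se)),
                sigma_b = stats::sd(c(0, subj_eff)),
                sigma_e = stats::sigma(ols),
                degenerate = FALSE, engine = "fixed"))
  }
  sm <- summary(fit)$coefficients
  est <- sm[terms, "Estimate"]
  se <- sm[terms, "Std. Error"]
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_b <- sqrt(vc$vcov[vc$grp == "subj"][1])
  sigma_e <- sqrt(vc$vcov[vc$grp == "Residual"][1])
  list(estimate = est, se = se, p = 2 * stats::pnorm(-abs(est / se)),
       sigma_b = sigma_b, sigma_e = sigma_e, degenerate = FALSE,
       engine = "lmer")
}

#' Select the polynomial shape of the ASIR relationship
#'
#' Fits the two-level model with linear, squared and cubic terms in
#' `x = weight/20`. If the cubic term is not significant at `alpha` it is
#' omitted and the model refitted; if the quadratic term is then not
#' significant it is omitted too, leaving a simple linear relationship.
#'
#' @param df Data frame with columns `subject_id`, `asir_weight`, `value`
#'   (one feature, one mode).
#' @param log_scale Analyse `log(value)`?
#' @param alpha Retention threshold for the higher-order terms (0.05).
#' @return `"linear"`, `"quadratic"`, `"cubic"`, or `"degenerate"` for a
#'   constant feature.
#' @export
select_shape <- function(df, log_scale = FALSE, alpha = 0.05) {
  if (length(unique(df$asir_weight)) < 4L)
    stop("shape selection needs at least 4 distinct weights")
  y <- if (log_scale) log(df$value) else df$value
  if (stats::sd(y) < 1e-12) return("degenerate")
  f3 <- .fit_two_level(df, 3L, log_scale)
  if (f3$p[3] < alpha) return("cubic")
  f2 <- .fit_two_level(df, 2L, log_scale)
  if (f2$p[2] < alpha) return("quadratic")
  "linear"
}

#' Fit the two-level random-intercept model for one feature
#'
#' Restricted-maximum-likelihood fit of `value` (or `log(value)`) on a
#' polynomial in `x = weight/20` with a per-subject random intercept. The
#' reported coefficient is the linear term: the change in the feature per
#' 20% ASIR increment. The 95% CI and p value use the Wald normal
#' approximation; `sigma_b` is the estimated between-subject
#' (random-intercept) SD, from which the standardised effect size
#' `B = |coef| / sigma_b` and its size category are derived.
#'
#' @param df Data frame with columns `subject_id`, `asir_weight`, `value`.
#' @param shape `"linear"`, `"quadratic"` or `"cubic"` (from
#'   [select_shape()]).
#' @param log_scale Analyse on the log scale (requires positive values).
#' @param conf_level Confidence level (default 0.95).
#' @param sigma_b_source `"model"` (random-intercept SD, default) or
#'   `"raw_subject_means"` (SD of observed subject means).
#' @return An `effect_estimate` list: `shape`, `log_scale`, `coef`,
#'   `ci_low`, `ci_high`, `p_value`, `sigma_b`, `B`, `category`,
#'   `degenerate`.
#' @export
fit_random_intercept <- function(df, shape = "linear", log_scale = FALSE,
                                 conf_level = 0.95,
                                 sigma_b_source = c("model", "raw_subject_means")) {
  sigma_b_source <- match.arg(sigma_b_source)
  ord <- match(shape, c("linear", "quadratic", "cubic"))
  if (is.na(ord)) stop("`shape` must be linear, quadratic or cubic")
  if (log_scale && any(df$value <= 0))
    stop("log-scale analysis requires strictly positive values")
  y <- if (log_scale) log(df$value) else df$value
  if (stats::sd(y) < 1e-12) {
    return(structure(list(shape = shape, log_scale = log_scale,
                          coef = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, p_value = NA_real_,
                          sigma_b = NA_real_, B = NA_real_,
                          category = NA_character_, degenerate = TRUE),
                     class = "effect_estimate"))
  }
  fit <- .fit_two_level(df, ord, log_scale)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  coef <- unname(fit$estimate[1])
  se <- unname(fit$se[1])
  sigma_b <- if (sigma_b_source == "model") fit$sigma_b else {
    m <- tapply(y, df$subject_id, mean)
    stats::sd(m)
  }
  B <- standardised_effect(coef, sigma_b)
  structure(list(shape = shape, log_scale = log_scale, coef = coef,
                 ci_low = coef - z * se, ci_high = coef + z * se,
                 p_value = unname(fit$p[1]), sigma_b = sigma_b, B = B,
                 category = if (is.na(B)) NA_character_ else classify_effect(B),
                 degenerate = FALSE),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  if (x$degenerate) { cat("<effect_estimate> degenerate (constant feature)\n")
  } else {
    cat(sprintf(
      "<effect_estimate> %s%s: coef %.4g (%.4g, %.4g) per 20%% ASIR, p = %.3g, B = %.3g (%s)\n",
      x$shape, if (x$log_scale) " [log scale]" else "", x$coef, x$ci_low,
      x$ci_high, x$p_value, x$B, x$category))
  }
  invisible(x)
}

#' Standardised effect size
#'
#' The absolute regression coefficient for a 20-unit ASIR increase divided
#' by the between-subject standard deviation.
#'
#' @param coef Regression coefficient (per 20% ASIR).
#' @param sigma_b Between-subject SD (> 0).
#' @return `B >= 0`, or `NA` when `sigma_b` is zero (degenerate).
#' @export
standardised_effect <- function(coef, sigma_b) {
  if (is.na(sigma_b) || sigma_b <= 0) return(NA_real_)
  abs(coef) / sigma_b
}

#' Classify a standardised effect size
#'
#' `B <= 0.3` is a small effect, `0.3 < B < 0.8` moderate, `B >= 0.8`
#' large.
#'
#' @param B Standardised effect size (>= 0).
#' @return `"small"`, `"moderate"` or `"large"`.
#' @export
classify_effect <- function(B) {
  if (is.na(B) || B < 0) stop("`B` must be >= 0")
  if (B <= 0.3) "small" else if (B < 0.8) "moderate" else "large"
}

#' Fit effect models for every feature in a cohort table
#'
#' Runs [select_shape()] then [fit_random_intercept()] per (mode, feature)
#' of a long-format cohort feature table. Features in `log_features`
#' (default the positively skewed fractal lacunarity) are analysed on the
#' log scale.
#'
#' @param table Long data frame with columns `subject_id`, `asir_weight`,
#'   `mode`, `feature_name`, `value`.
#' @param log_features Features analysed on the log scale.
#' @param alpha Significance threshold (shape selection and reporting).
#' @param sigma_b_source Passed to [fit_random_intercept()].
#' @return Data frame, one row per (mode, feature): shape, coefficient per
#'   20% ASIR with 95% CI, p value, `sigma_b`, `B`, category, family and a
#'   significance flag.
#' @export
fit_feature_effects <- function(table, log_features = "fractal_lacunarity",
                                alpha = 0.05,
                                sigma_b_source = c("model", "raw_subject_means")) {
  sigma_b_source <- match.arg(sigma_b_source)
  need <- c("subject_id", "asir_weight", "mode", "feature_name", "value")
  if (!all(need %in% names(table)))
    stop("table must have columns ", paste(need, collapse = ", "))
  combos <- unique(table[, c("mode", "feature_name")])
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    mode <- combos$mode[k]; feat <- combos$feature_name[k]
    df <- table[table$mode == mode & table$feature_name == feat, ]
    df <- df[stats::complete.cases(df[, c("value", "asir_weight")]), ]
    base <- data.frame(mode = mode, feature_name = feat,
                       family = feature_family(feat), stringsAsFactors = FALSE)
    if (nrow(df) < 12L || length(unique(df$subject_id)) < 2L ||
        stats::sd(df$value) < 1e-12) {
      return(cbind(base, shape = "degenerate", log_scale = FALSE,
                   coef = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                   p_value = NA_real_, sigma_b = NA_real_, B = NA_real_,
                   category = NA_character_, significant = NA))
    }
    log_scale <- feat %in% log_features && all(df$value > 0)
    shape <- select_shape(df, log_scale = log_scale, alpha = alpha)
    if (shape == "degenerate") {
      return(cbind(base, shape = shape, log_scale = log_scale,
                   coef = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                   p_value = NA_real_, sigma_b = NA_real_, B = NA_real_,
                   category = NA_character_, significant = NA))
    }
    est <- fit_random_intercept(df, shape, log_scale,
                                sigma_b_source = sigma_b_source)
    cbind(base, shape = est$shape, log_scale = est$log_scale,
          coef = est$coef, ci_low = est$ci_low, ci_high = est$ci_high,
          p_value = est$p_value, sigma_b = est$sigma_b, B = est$B,
          category = if (is.null(est$category) || is.na(est$B)) NA_character_
                     else est$category,
          significant = !is.na(est$p_value) && est$p_value < alpha)
  })
  do.call(rbind, rows)
}

#' Summarise effect estimates into report tables
#'
#' Produces the per-mode report (coefficient with CI, B, p, significance
#' marked at p < 0.05) and the family-level summary (median and range of B
#' per feature family and mode). Degenerate estimates are excluded from
#' the family summary with a warning.
#'
#' @param estimates Output of [fit_feature_effects()].
#' @param alpha Significance level for marking.
#' @return List with `report` (per-feature data frame) and
#'   `family_summary` (per family x mode medians/ranges of B).
#' @export
summarise_effects <- function(estimates, alpha = 0.05) {
  if (!nrow(estimates)) stop("no estimates to summarise")
  bad <- is.na(estimates$B)
  if (any(bad))
    warning(sum(bad), " degenerate estimate(s) excluded from the family summary")
  ok <- estimates[!bad, , drop = FALSE]
  fs <- do.call(rbind, lapply(split(ok, list(ok$mode, ok$family), drop = TRUE),
    function(g) data.frame(mode = g$mode[1], family = g$family[1],
                           n_features = nrow(g),
                           n_significant = sum(g$significant, na.rm = TRUE),
                           median_B = stats::median(g$B),
                           min_B = min(g$B), max_B = max(g$B),
                           stringsAsFactors = FALSE)))
  rownames(fs) <- NULL
  est <- estimates[order(estimates$mode, estimates$family,
                         estimates$feature_name), ]
  rownames(est) <- NULL
  list(report = est, family_summary = fs)
}
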