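# End-to-end orchestration: config handling, cohort extraction at all six
# weights in both analysis modes, effect modelling, and report output.

.ALL_FAMILIES <- c("first_order", "glcm", "gldm", "ngtdm", "glrl", "glzsm",
                   "fractal")

#' Default run configuration
#'
#' Returns the full nested configuration with the package defaults: a
#' 28-subject synthetic cohort, 3x3 mean pre-smoothing, 32-bin fixed-count
#' discretisation, distance-1 matrices, the default fractal ladders, and
#' the effect model with lacunarity on the log scale.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    output_dir = "asirtex_out",
    input = list(type = "synthetic", manifest = NULL, n_subjects = 28L,
                 fraction_small = 5 / 28),
    preprocessing = list(
      smoothing = list(kind = "mean", size = 3L),
      discretisation = list(n_bins = 32L, method = "fixed_count",
                            bin_width = 32)),
    matrix = list(d = 1L),
    families = .ALL_FAMILIES,
    fractal = list(window = 8L, scales = c(2L, 4L, 8L),
                   lacunarity_boxes = c(2L, 4L, 8L, 16L), max_eps = 8L),
    effect = list(log_features = "fractal_lacunarity", alpha = 0.05,
                  sigma_b_source = "model"))
}

.merge_config <- function(base, extra) {
  for (nm in names(extra)) {
    if (is.list(base[[nm]]) && is.list(extra[[nm]]) &&
        !is.null(names(extra[[nm]]))) {
      base[[nm]] <- .merge_config(base[[nm]], extra[[nm]])
    } else base[[nm]] <- extra[[nm]]
  }
  base
}

#' Load a YAML run configuration
#'
#' Reads a YAML file and merges it over [default_config()]; missing keys
#' keep their defaults. The result is validated before use.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
load_config <- function(path) {
  cfg <- .merge_config(default_config(), yaml::read_yaml(path))
  validate_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' @param config Configuration list (see [default_config()]).
#' @return Invisibly `TRUE`; errors describe the offending key.
#' @export
validate_config <- function(config) {
  ck <- function(cond, msg) if (!cond) stop("config: ", msg)
  ck(is.numeric(config$seed) && length(config$seed) == 1, "seed must be one integer")
  ck(config$input$type %in% c("synthetic", "manifest"),
     "input.type must be 'synthetic' or 'manifest'")
  if (config$input$type == "manifest")
    ck(is.character(config$input$manifest), "input.manifest path required")
  sm <- config$preprocessing$smoothing
  ck(sm$kind %in% c("mean", "gaussian", "median"),
     "preprocessing.smoothing.kind must be mean/gaussian/median")
  ck(sm$size >= 1 && sm$size %% 2 == 1, "smoothing size must be odd")
  dc <- config$preprocessing$discretisation
  ck(dc$n_bins >= 2, "discretisation.n_bins must be >= 2")
  ck(dc$method %in% c("fixed_count", "fixed_width"),
     "discretisation.method must be fixed_count or fixed_width")
  ck(config$matrix$d >= 1, "matrix.d must be >= 1")
  ck(all(config$families %in% .ALL_FAMILIES),
     paste("families must be among:", paste(.ALL_FAMILIES, collapse = ", ")))
  ck(length(config$fractal$scales) >= 3, "fractal.scales needs >= 3 sizes")
  ck(config$effect$alpha > 0 && config$effect$alpha < 1,
     "effect.alpha must be in (0, 1)")
  ck(config$effect$sigma_b_source %in% c("model", "raw_subject_means"),
     "effect.sigma_b_source must be model or raw_subject_means")
  invisible(TRUE)
}

# feature extraction for one discretised region
.region_features <- function(droi, config, fractal_args = NULL) {
  fams <- config$families
  out <- c()
  if ("first_order" %in% fams) out <- c(out, first_order_features(droi))
  d <- config$matrix$d
  if ("glcm" %in% fams) out <- c(out, glcm_features(droi, d))
  if ("gldm" %in% fams) out <- c(out, gldm_features(droi, d))
  if ("ngtdm" %in% fams) out <- c(out, ngtdm_features(droi))
  if ("glrl" %in% fams) out <- c(out, glrl_features(droi))
  if ("glzsm" %in% fams) out <- c(out, glzsm_features(droi))
  if (!is.null(fractal_args)) out <- c(out, do.call(fractal_features, fractal_args))
  out
}

#' Extract the full feature set for one subject
#'
#' Verifies grid congruence, copies the 0% ROI onto all weights, derives
#' the single-slice and (when 5 contiguous tumour slices exist) multi-slice
#' regions, then per weight applies smoothing, discretisation and every
#' enabled feature family. Fractal features are computed in single-slice
#' mode only.
#'
#' @param series A [recon_series()].
#' @param mask The subject's [roi_mask()] drawn on the 0% volume.
#' @param config Configuration list (see [default_config()]).
#' @return Long data frame: `subject_id`, `asir_weight`, `mode`,
#'   `feature_name`, `value`.
#' @export
extract_subject_features <- function(series, mask, config = default_config()) {
  propagate_roi(mask, series)  # validates congruence and mask grid
  regions <- select_regions(mask)
  sm <- config$preprocessing$smoothing
  dc <- config$preprocessing$discretisation
  rows <- list()
  for (w in asir_weights()) {
    vol <- smooth_volume(series$volumes[[as.character(w)]],
                         size = sm$size, kind = sm$kind)
    modes <- list(single_slice = regions$single)
    if (!is.null(regions$multi)) modes$multi_slice <- regions$multi
    for (mode in names(modes)) {
      region <- modes[[mode]]
      droi <- discretise(region, vol, Ng = dc$n_bins, method = dc$method,
                         bin_width = dc$bin_width)
      fractal_args <- NULL
      if (mode == "single_slice" && "fractal" %in% config$families) {
        fr <- config$fractal
        fractal_args <- list(region = region, volume = vol,
                             Ng = dc$n_bins, window = fr$window,
                             scales = fr$scales,
                             lac_boxes = fr$lacunarity_boxes,
                             max_eps = fr$max_eps)
      }
      fv <- .region_features(droi, config, fractal_args)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = series$subject_id, asir_weight = w, mode = mode,
        feature_name = names(fv), value = unname(fv),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract features for a whole cohort
#'
#' Runs [extract_subject_features()] for every subject. Per-subject
#' failures (e.g. grid mismatches) are logged and skipped, mirroring
#' subject exclusion rather than aborting the run; the exclusion log is
#' attached as attribute `"exclusions"`.
#'
#' @param config Configuration list; `input.type` selects the synthetic
#'   cohort or a manifest of NIfTI files.
#' @param cohort Optional pre-built cohort (list of `series`/`mask`
#'   pairs), bypassing `config$input`.
#' @return Long cohort feature table (see [extract_subject_features()]).
#' @export
run_extraction <- function(config = default_config(), cohort = NULL) {
  validate_config(config)
  if (is.null(cohort)) {
    cohort <- if (config$input$type == "synthetic") {
      generate_cohort(phantom_params(
        n_subjects = config$input$n_subjects,
        fraction_small = config$input$fraction_small,
        seed = config$seed))
    } else {
      man <- read_manifest(config$input$manifest)
      lapply(seq_len(nrow(man)), function(i) load_subject(man[i, ]))
    }
  }
  tabs <- list()
  excl <- character(0)
  for (subj in cohort) {
    res <- tryCatch(
      extract_subject_features(subj$series, subj$mask, config),
      error = function(e) e)
    if (inherits(res, "error")) {
      excl <- c(excl, sprintf("%s: %s", subj$series$subject_id,
                              conditionMessage(res)))
      next
    }
    tabs[[length(tabs) + 1L]] <- res
  }
  if (!length(tabs)) stop("empty cohort: every subject failed extraction")
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}

# small dependency-free content fingerprint (base-256 polynomial hash mod
# 2^31 - 1 over the serialised object), for run-log provenance
.content_hash <- function(obj) {
  v <- as.integer(serialize(obj, NULL, xdr = TRUE))
  p <- 2147483647
  mulmod <- function(a, b) {  # a, b < p; exact in doubles via 16-bit split
    hi <- a %/% 65536; lo <- a %% 65536
    (((hi * b) %% p) * 65536 + lo * b) %% p
  }
  w <- numeric(4096); w[1] <- 1
  for (i in 2:4096) w[i] <- (w[i - 1] * 256) %% p
  h <- 0
  for (blk in split(v, ceiling(seq_along(v) / 4096))) {
    n <- length(blk)
    s <- sum((blk * w[n:1]) %% p) %% p
    bn <- mulmod(w[n], 256)   # 256^n mod p
    h <- (mulmod(h, bn) + s) %% p
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full pipeline
#'
#' Extraction, effect modelling and report output in one call: writes the
#' long feature table, per-mode report tables shaped like the study's
#' summary tables (coefficient with 95% CI, standardised effect size B,
#' p value), the family-level B summary, and a JSON run log carrying the
#' full configuration, exclusions and a content hash of the feature table.
#'
#' @param config Configuration list or path to a YAML config.
#' @param out_dir Output directory (defaults to `config$output_dir`).
#' @param cohort Optional pre-built cohort, passed to [run_extraction()].
#' @return Invisibly, a list: `features`, `estimates`, `summary`, `paths`.
#' @export
run_full <- function(config = default_config(), out_dir = NULL, cohort = NULL) {
  if (is.character(config)) config <- load_config(config)
  validate_config(config)
  if (is.null(out_dir)) out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  features <- run_extraction(config, cohort = cohort)
  estimates <- fit_feature_effects(
    features, log_features = config$effect$log_features,
    alpha = config$effect$alpha,
    sigma_b_source = config$effect$sigma_b_source)
  summ <- withCallingHandlers(
    summarise_effects(estimates, alpha = config$effect$alpha),
    warning = function(w) invokeRestart("muffleWarning"))
  paths <- list(
    features = file.path(out_dir, "features.csv"),
    report_single = file.path(out_dir, "report_single_slice.csv"),
    report_multi = file.path(out_dir, "report_multi_slice.csv"),
    family_summary = file.path(out_dir, "family_summary.csv"),
    log = file.path(out_dir, "run_log.json"))
  utils::write.csv(features, paths$features, row.names = FALSE)
  rep <- summ$report
  utils::write.csv(rep[rep$mode == "single_slice", ], paths$report_single,
                   row.names = FALSE)
  utils::write.csv(rep[rep$mode == "multi_slice", ], paths$report_multi,
                   row.names = FALSE)
  utils::write.csv(summ$family_summary, paths$family_summary,
                   row.names = FALSE)
  n_modes <- table(unique(features[, c("subject_id", "mode")])$mode)
  cfg_log <- config
  cfg_log$effect$log_features <- as.list(cfg_log$effect$log_features)
  log <- list(
    package_version = as.character(utils::packageVersion("asirtex")),
    config = cfg_log,
    n_subjects_single_slice = unname(n_modes["single_slice"]),
    n_subjects_multi_slice = unname(if (is.na(n_modes["multi_slice"])) 0L
                                    else n_modes["multi_slice"]),
    exclusions = as.list(attr(features, "exclusions")),
    degenerate_features = as.list(
      estimates$feature_name[is.na(estimates$B)]),
    features_hash = .content_hash(features))
  jsonlite::write_json(log, paths$log, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(list(features = features, estimates = estimates, summary = summ,
                 paths = paths))
}
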