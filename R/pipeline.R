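#' Cross-validate one predictor design
#'
#' Public wrapper around the shared-fold evaluation engine: builds the chosen
#' feature set (EMA-only by default, optionally windowed to the first k days
#' or one wave) and runs [repeated_cv()] with PAC and classification
#' thresholds derived on training folds only.
#'
#' @inheritParams compare_predictor_sets
#' @param design `"ema"`, `"baseline"` or `"baseline_plus_ema"`.
#' @param window Optional day subset for the EMA features.
#' @param folds Optional precomputed [make_folds()] assignments.
#' @return A `metric_distribution`.
#' @export
ema_design_cv <- function(daily, outcomes, horizon = "1mo",
                          design = c("ema", "baseline", "baseline_plus_ema"),
                          baselines = NULL, window = NULL,
                          scheme = cv_scheme(), folds = NULL,
                          hyperparams = default_hyperparams(), tuning = NULL) {
  design <- match.arg(design)
  horizon <- match.arg(horizon, outcome_horizons())
  participants <- outcomes$participant_id
  labels <- outcomes[[paste0("si_", horizon)]]
  bl <- NULL
  if (design != "ema") {
    if (is.null(baselines)) stop("design needs baseline records", call. = FALSE)
    bl <- encode_baseline(baselines)
  }
  if (scheme$variant == "kfold" && is.null(folds))
    folds <- make_folds(labels, scheme$k, scheme$repetitions, seed = scheme$seed)
  evaluate_design(daily, labels, participants, scheme, folds, window = window,
                  baseline = bl, use_ema = design != "baseline",
                  hyperparams = hyperparams, tuning = tuning)
}

#' @param baselines Baseline predictor data.frame, required for the designs
#'   that use it.
#' @name ema_design_cv
NULL

#' Split-count importance of the EMA features on the full cohort
#'
#' Fits on all participants (as done when ranking predictors across an
#' entire data set) and returns the scaled split-count table. Split-count
#' importance from a single fit is unstable when informative features are
#' correlated (the ensemble credits one of them with the shared signal), so
#' the counts can be aggregated over `n_models` seeded refits and, when
#' several horizons are given, summed across the horizon-specific models
#' before scaling and ranking.
#'
#' @inheritParams compare_predictor_sets
#' @param horizon One or more of `"1mo"`, `"3mo"`, `"8mo"`; counts are
#'   summed across the corresponding outcome models.
#' @param window Optional day subset.
#' @param n_models Seeded refits per horizon to aggregate over.
#' @param seed Base seed for the fits.
#' @return data.frame from [split_importance()] (`split_count` is the
#'   aggregated count).
#' @export
full_data_importance <- function(daily, outcomes, horizon = "1mo",
                                 window = NULL,
                                 hyperparams = default_hyperparams(),
                                 n_models = 1L, seed = 1L) {
  stopifnot(all(horizon %in% outcome_horizons()))
  thr <- pac_thresholds(daily, window = window, on_empty = "inf")
  ft <- suppressWarnings(
    build_feature_table(daily, outcomes$participant_id, window = window,
                        thresholds = thr))
  counts <- stats::setNames(rep(0L, length(ema_feature_names())),
                            ema_feature_names())
  off <- 0L
  for (h in horizon) {
    labels <- outcomes[[paste0("si_", h)]]
    for (i in seq_len(n_models)) {
      fit <- fit_gbm(ft, labels, hyperparams, seed = seed + off)
      imp <- split_importance(fit)
      counts <- counts + imp$split_count[match(names(counts), imp$feature)]
      off <- off + 1L
    }
  }
  rng <- range(counts)
  score <- if (any(counts > 0)) {
    if (rng[2] > rng[1]) 100 * (counts - rng[1]) / (rng[2] - rng[1])
    else ifelse(counts > 0, 100, 0)
  } else rep(0, length(counts))
  out <- data.frame(feature = names(counts), split_count = as.integer(counts),
                    score = as.numeric(score),
                    rank = rank(-counts, ties.method = "average"),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$split_count, out$feature), ]
  rownames(out) <- NULL
  out
}

#' Run the full simulate-featurize-evaluate pipeline
#'
#' Orchestrates one reproducible end-to-end run: simulate a cohort (or read
#' CSVs), day-aggregate, and execute the requested analyses, writing all
#' tables plus a JSON manifest to `out_dir`.
#'
#' @param out_dir Output directory (created if needed).
#' @param sim A [sim_config()], or `NULL` to read `ema_csv`/`baseline_csv`.
#' @param ema_csv,baseline_csv Input files when `sim` is `NULL`.
#' @param horizons Outcome horizons to analyse.
#' @param analyses Subset of `c("compare", "day_curve", "waves",
#'   "importance")`.
#' @param scheme A [cv_scheme()].
#' @param wave_boundaries Wave partition of the study days.
#' @param seed Global seed; stage seeds are derived from it.
#' @param hyperparams,tuning Passed through to the evaluation harness.
#' @return (Invisibly) a list with every computed result and the manifest.
#' @export
run_pipeline <- function(out_dir, sim = sim_config(), ema_csv = NULL,
                         baseline_csv = NULL, horizons = "1mo",
                         analyses = c("compare", "day_curve", "waves",
                                      "importance"),
                         scheme = cv_scheme(), wave_boundaries = c(8L, 17L),
                         seed = 1L, hyperparams = default_hyperparams(),
                         tuning = NULL) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(sim)) {
    sim$seed <- as.integer(seed)
    cohort <- simulate_cohort(sim)
    surveys <- cohort$surveys
    baselines <- cohort$baselines
    outcomes <- cohort$outcomes
    n_days <- sim$n_days
    participants <- baselines$participant_id
    write_ema_csv(surveys, file.path(out_dir, "ema_surveys.csv"))
    write_baseline_csv(baselines, outcomes,
                       file.path(out_dir, "participants.csv"))
  } else {
    if (is.null(ema_csv) || is.null(baseline_csv))
      stop("either a sim_config or both input CSVs are required", call. = FALSE)
    bl <- read_baseline_csv(baseline_csv)
    baselines <- bl$baselines
    outcomes <- bl$outcomes
    participants <- baselines$participant_id
    ds <- read_ema_long(ema_csv, participants = participants)
    surveys <- ds$surveys
    n_days <- ds$n_days
  }
  ds <- ema_dataset(surveys, participants = participants, n_days = n_days)
  daily <- day_aggregate(ds)
  res <- list(compliance = compliance_rate(ds))
  scheme$seed <- as.integer(seed) + 1L

  for (h in horizons) {
    hr <- list()
    if ("compare" %in% analyses) {
      hr$compare <- compare_predictor_sets(daily, baselines, outcomes, h,
                                           scheme, hyperparams, tuning)
      utils::write.csv(hr$compare$tests,
                       file.path(out_dir, sprintf("compare_tests_%s.csv", h)),
                       row.names = FALSE)
      write_metric_csv(hr$compare$results,
                       file.path(out_dir, sprintf("compare_metrics_%s.csv", h)))
    }
    if ("day_curve" %in% analyses) {
      hr$day_curve <- incremental_day_curve(daily, outcomes, h, scheme,
                                            hyperparams = hyperparams,
                                            tuning = tuning)
      utils::write.csv(hr$day_curve$curve,
                       file.path(out_dir, sprintf("day_curve_%s.csv", h)),
                       row.names = FALSE)
    }
    if ("waves" %in% analyses) {
      hr$waves <- wave_analysis(daily, outcomes, h, wave_boundaries, scheme,
                                hyperparams, tuning)
      write_metric_csv(hr$waves$results,
                       file.path(out_dir, sprintf("wave_metrics_%s.csv", h)))
    }
    if ("importance" %in% analyses) {
      hr$importance <- full_data_importance(daily, outcomes, h,
                                            hyperparams = hyperparams,
                                            seed = seed)
      utils::write.csv(hr$importance,
                       file.path(out_dir, sprintf("importance_%s.csv", h)),
                       row.names = FALSE)
    }
    res[[h]] <- hr
  }
  manifest <- list(seed = seed, horizons = horizons, analyses = analyses,
                   scheme = unclass(scheme), wave_boundaries = wave_boundaries,
                   simulated = !is.null(sim),
                   compliance = res$compliance,
                   r_version = as.character(getRversion()),
                   xgboost_version = as.character(utils::packageVersion("xgboost")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

write_metric_csv <- function(results, path) {
  rows <- do.call(rbind, lapply(names(results), function(d)
    cbind(design = d, results[[d]]$folds)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
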