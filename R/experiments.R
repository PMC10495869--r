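#' Welch two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom,
#' two-sided. Used to compare fold-level metric values between designs,
#' windows or waves.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return Named list `t`, `p`, `df`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs n >= 2", call. = FALSE)
  res <- tryCatch(stats::t.test(a, b, var.equal = FALSE),
                  error = function(e)
                    stop("Welch t undefined: ", conditionMessage(e),
                         call. = FALSE))
  list(t = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values: `p_adj(i) = min_{j >= rank(i)} m * p(j) / j`,
#' capped at 1.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0,1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

# Precompute, for one window, everything fold-independent: the 52
# threshold-free feature columns (PAC columns zeroed) and each participant's
# absolute successive differences per dynamic series. Only the 8 PAC columns
# depend on the training-fold threshold, so folds can rebuild them cheaply.
prep_features <- function(daily, participants, window = NULL) {
  base <- suppressWarnings(
    build_feature_table(daily, participants, window = window,
                        thresholds = stats::setNames(
                          rep(Inf, 8), dynamic_series_names())))
  if (!is.null(window)) daily <- daily[daily$day %in% window, , drop = FALSE]
  sp <- split(daily, factor(daily$participant_id, levels = participants))
  vars <- dynamic_series_names()
  diffs <- lapply(participants, function(p) {
    d <- sp[[p]]
    if (is.null(d) || nrow(d) < 2)
      return(stats::setNames(rep(list(numeric()), length(vars)), vars))
    d <- d[order(d$day), ]
    stats::setNames(lapply(vars, function(v) abs(diff(d[[v]]))), vars)
  })
  list(base = as_feature_matrix(base), diffs = diffs, vars = vars)
}

# PAC thresholds (90th percentile of pooled |diffs|) from precomputed diffs
thresholds_from_diffs <- function(prep, idx) {
  vapply(prep$vars, function(v) {
    pooled <- unlist(lapply(prep$diffs[idx], `[[`, v), use.names = FALSE)
    if (!length(pooled)) return(Inf)
    stats::quantile(pooled, 0.9, names = FALSE, type = 7)
  }, numeric(1))
}

features_with_pac <- function(prep, thresholds) {
  m <- prep$base
  thresholds <- pmax(thresholds, .Machine$double.eps)
  for (v in prep$vars) {
    pac <- vapply(prep$diffs, function(d)
      if (length(d[[v]])) mean(d[[v]] >= thresholds[[v]]) else 0, numeric(1))
    m[, paste0(v, "_pac")] <- pac
  }
  m
}

# Evaluate one design (a feature specification) under shared folds.
# PAC and Youden thresholds are derived on training participants only.
evaluate_design <- function(daily, labels, participants, scheme, folds,
                            window = NULL, baseline = NULL, use_ema = TRUE,
                            hyperparams = default_hyperparams(), tuning = NULL) {
  stopifnot(use_ema || !is.null(baseline))
  if (!is.null(baseline)) {
    baseline <- baseline[match(participants, baseline$participant_id), ,
                         drop = FALSE]
    if (anyNA(baseline$participant_id))
      stop("baseline table missing participants", call. = FALSE)
    bl_m <- as_feature_matrix(baseline)
  }
  prep <- if (use_ema) prep_features(daily, participants, window = window)
  builder <- function(tr, te) {
    feats <- NULL
    if (use_ema)
      feats <- features_with_pac(prep, thresholds_from_diffs(prep, tr))
    if (!is.null(baseline))
      feats <- if (is.null(feats)) bl_m else cbind(feats, bl_m)
    list(train = feats[tr, , drop = FALSE], test = feats[te, , drop = FALSE])
  }
  repeated_cv(builder, labels, scheme = scheme, hyperparams = hyperparams,
              tuning = tuning, folds = folds)
}

pairwise_metric_tests <- function(results) {
  metrics <- c("auc", "sensitivity", "specificity", "ppv")
  designs <- names(results)
  pairs <- utils::combn(designs, 2, simplify = FALSE)
  rows <- list()
  for (m in metrics) for (pr in pairs) {
    va <- results[[pr[1]]]$folds[[m]]; vb <- results[[pr[2]]]$folds[[m]]
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    wt <- tryCatch(welch_t(va, vb),
                   error = function(e) list(t = NA_real_, p = NA_real_))
    rows[[length(rows) + 1L]] <-
      data.frame(metric = m, design_a = pr[1], design_b = pr[2],
                 mean_a = mean(va), mean_b = mean(vb),
                 t = wt$t, p = wt$p, stringsAsFactors = FALSE)
  }
  tests <- do.call(rbind, rows)
  ok <- !is.na(tests$p)
  tests$p_adj <- NA_real_
  tests$p_adj[ok] <- bh_adjust(tests$p[ok])
  tests
}

#' Compare baseline, EMA and combined predictor sets
#'
#' Runs the same repeated stratified cross-validation (identical fold
#' assignments, for a paired comparison) on three designs — the 7 baseline
#' predictors alone, the 60 EMA features alone, and their union — then tests
#' every pairwise difference per metric with Welch t tests on the fold-level
#' values and adjusts the 12 p-values jointly by Benjamini-Hochberg.
#'
#' @param daily Day-level data.frame ([day_aggregate()]).
#' @param baselines Baseline predictor data.frame (raw; encoded internally).
#' @param outcomes Outcome label data.frame.
#' @param horizon `"1mo"`, `"3mo"` or `"8mo"`.
#' @param scheme A [cv_scheme()].
#' @param hyperparams,tuning Passed to [repeated_cv()].
#' @return List of class `ema_experiment`: `$results` (named
#'   `metric_distribution`s), `$tests` (pairwise Welch/BH table), `$horizon`.
#' @export
compare_predictor_sets <- function(daily, baselines, outcomes,
                                   horizon = "1mo", scheme = cv_scheme(),
                                   hyperparams = default_hyperparams(),
                                   tuning = NULL) {
  horizon <- match.arg(horizon, outcome_horizons())
  participants <- outcomes$participant_id
  labels <- outcomes[[paste0("si_", horizon)]]
  bl <- encode_baseline(baselines)
  folds <- make_folds(labels, scheme$k, scheme$repetitions, seed = scheme$seed)
  results <- list(
    baseline = evaluate_design(daily, labels, participants, scheme, folds,
                               baseline = bl, use_ema = FALSE,
                               hyperparams = hyperparams, tuning = tuning),
    ema = evaluate_design(daily, labels, participants, scheme, folds,
                          hyperparams = hyperparams, tuning = tuning),
    baseline_plus_ema = evaluate_design(daily, labels, participants, scheme,
                                        folds, baseline = bl,
                                        hyperparams = hyperparams,
                                        tuning = tuning))
  structure(list(results = results, tests = pairwise_metric_tests(results),
                 horizon = horizon, folds = folds),
            class = "ema_experiment")
}

#' Incremental day-overlay AUC curve
#'
#' Re-evaluates the EMA-only design using only the first `k` study days, for
#' each `k` in `k_range`, under identical fold assignments, and reports the
#' smallest `k` whose mean cross-validated AUC exceeds `auc_threshold`
#' (`NA` if never crossed).
#'
#' @inheritParams compare_predictor_sets
#' @param k_range Day counts to evaluate (default `1:max(daily$day)`).
#' @param auc_threshold Acceptable-accuracy cutoff (default 0.70).
#' @return List of class `ema_day_curve`: `$curve` (data.frame `k`,
#'   `mean_auc`, `lower`, `upper`), `$crossing_k`, `$results`.
#' @export
incremental_day_curve <- function(daily, outcomes, horizon = "1mo",
                                  scheme = cv_scheme(), k_range = NULL,
                                  auc_threshold = 0.70,
                                  hyperparams = default_hyperparams(),
                                  tuning = NULL) {
  horizon <- match.arg(horizon, outcome_horizons())
  if (is.null(k_range)) k_range <- seq_len(max(daily$day))
  participants <- outcomes$participant_id
  labels <- outcomes[[paste0("si_", horizon)]]
  folds <- make_folds(labels, scheme$k, scheme$repetitions, seed = scheme$seed)
  results <- lapply(k_range, function(k)
    evaluate_design(daily, labels, participants, scheme, folds,
                    window = seq_len(k), hyperparams = hyperparams,
                    tuning = tuning))
  names(results) <- paste0("days_1..", k_range)
  mean_auc <- vapply(results, function(r)
    r$summary$mean[r$summary$metric == "auc"], numeric(1))
  lower <- vapply(results, function(r)
    r$summary$lower[r$summary$metric == "auc"], numeric(1))
  upper <- vapply(results, function(r)
    r$summary$upper[r$summary$metric == "auc"], numeric(1))
  crossing <- k_range[mean_auc > auc_threshold]
  structure(list(curve = data.frame(k = k_range, mean_auc = mean_auc,
                                    lower = lower, upper = upper),
                 crossing_k = if (length(crossing)) min(crossing) else NA_integer_,
                 auc_threshold = auc_threshold, horizon = horizon,
                 results = results),
            class = "ema_day_curve")
}

#' Per-wave predictive performance
#'
#' Evaluates the EMA-only design separately on each Lunar New Year wave's
#' days (features recomputed within the wave window; still 60 columns), under
#' identical fold assignments, with pairwise Welch t tests across waves and
#' Benjamini-Hochberg adjustment.
#'
#' @inheritParams compare_predictor_sets
#' @param wave_boundaries Two day indices; see [wave_days()].
#' @return List of class `ema_experiment` with results `wave1`, `wave2`,
#'   `wave3`.
#' @export
wave_analysis <- function(daily, outcomes, horizon = "1mo",
                          wave_boundaries = c(8L, 17L), scheme = cv_scheme(),
                          hyperparams = default_hyperparams(), tuning = NULL) {
  horizon <- match.arg(horizon, outcome_horizons())
  n_days <- max(daily$day)
  wd <- wave_days(n_days, wave_boundaries)
  for (w in names(wd))
    if (!length(wd[[w]])) stop(sprintf("wave '%s' has no days", w), call. = FALSE)
  participants <- outcomes$participant_id
  labels <- outcomes[[paste0("si_", horizon)]]
  folds <- make_folds(labels, scheme$k, scheme$repetitions, seed = scheme$seed)
  results <- lapply(wd, function(days)
    evaluate_design(daily, labels, participants, scheme, folds,
                    window = days, hyperparams = hyperparams, tuning = tuning))
  structure(list(results = results, tests = pairwise_metric_tests(results),
                 horizon = horizon, wave_days = wd, folds = folds),
            class = "ema_experiment")
}

#' @export
print.ema_experiment <- function(x, ...) {
  cat(sprintf("EMA experiment at horizon %s\n", x$horizon))
  for (d in names(x$results)) {
    s <- x$results[[d]]$summary
    cat(sprintf("  %-18s AUC %.3f  sens %.3f  spec %.3f  ppv %.3f\n", d,
                s$mean[s$metric == "auc"], s$mean[s$metric == "sensitivity"],
                s$mean[s$metric == "specificity"], s$mean[s$metric == "ppv"]))
  }
  sig <- x$tests[!is.na(x$tests$p_adj) & x$tests$p_adj < 0.05, ]
  cat(sprintf("  %d of %d pairwise differences BH-significant at 0.05\n",
              nrow(sig), nrow(x$tests)))
  invisible(x)
}
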