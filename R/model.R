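#' Default gradient-boosted tree hyperparameters
#'
#' Conservative settings for cohorts of ~100-1000 participants with 60-67
#' features: 150 shallow trees, learning rate 0.1, row/column subsampling.
#'
#' @return Named list understood by [fit_gbm()].
#' @export
default_hyperparams <- function() {
  list(nrounds = 150L, eta = 0.1, max_depth = 3L, min_child_weight = 5,
       subsample = 0.8, colsample_bytree = 0.8)
}

#' Hyperparameters for marginal-credit importance ranking
#'
#' A random-subspace stump ensemble: depth-1 trees over small random feature
#' subsets (10% of columns per tree). Because each stump picks the best
#' feature within its subset, aggregated split counts approximate a
#' marginal-strength tournament, so correlated informative features each
#' receive credit instead of competing for it — the recommended setting when
#' ranking predictors, as distinct from the deeper ensembles used for
#' prediction.
#'
#' @return Named hyperparameter list for [fit_gbm()].
#' @export
marginal_importance_hyperparams <- function() {
  list(nrounds = 600L, eta = 0.05, max_depth = 1L, min_child_weight = 5,
       subsample = 0.8, colsample_bytree = 0.1)
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    x <- x[, setdiff(names(x), "participant_id"), drop = FALSE]
    x <- as.matrix(x)
  }
  storage.mode(x) <- "double"
  x
}

#' Fit a gradient-boosted decision-tree classifier
#'
#' Binary logistic boosting (xgboost backend), single-threaded and seeded so
#' that identical inputs give bit-identical models. The fitted object exposes
#' per-feature split counts for [split_importance()].
#'
#' @param x Feature data.frame (a `participant_id` column is dropped) or
#'   numeric matrix.
#' @param y Binary 0/1 label vector; both classes must be present.
#' @param hyperparams See [default_hyperparams()].
#' @param seed Integer seed.
#' @return Object of class `ema_gbm`.
#' @export
fit_gbm <- function(x, y, hyperparams = default_hyperparams(), seed = 1L) {
  x <- as_feature_matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- as.integer(y)
  if (anyNA(y) || !all(y %in% 0:1)) stop("labels must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("labels contain a single class; cannot fit a classifier", call. = FALSE)
  if (nrow(x) != length(y)) stop("x and y sizes differ", call. = FALSE)
  hp <- utils::modifyList(default_hyperparams(), hyperparams)
  params <- list(objective = "binary:logistic",
                 eta = hp$eta, max_depth = hp$max_depth,
                 min_child_weight = hp$min_child_weight,
                 subsample = hp$subsample, colsample_bytree = hp$colsample_bytree,
                 nthread = 1L, seed = as.integer(seed))
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1L)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = hp$nrounds, verbose = 0)
  structure(list(booster = booster, feature_names = colnames(x),
                 hyperparams = hp, seed = as.integer(seed)),
            class = "ema_gbm")
}

#' @rdname fit_gbm
#' @param object Fitted `ema_gbm`.
#' @param newdata Feature data.frame or matrix with the training columns.
#' @param ... Unused.
#' @return Predicted probabilities of the positive class.
#' @export
predict.ema_gbm <- function(object, newdata, ...) {
  m <- as_feature_matrix(newdata)
  if (is.null(colnames(m)) && ncol(m) == length(object$feature_names))
    colnames(m) <- object$feature_names
  m <- m[, object$feature_names, drop = FALSE]
  predict(object$booster, xgboost::xgb.DMatrix(m, nthread = 1L))
}

#' Split-count feature importance
#'
#' Importance of a feature is the number of times the ensemble uses it as a
#' split node; raw counts are min-max scaled to 0-100 (an unsplit feature
#' scores 0, the most-used feature 100) and ranked.
#'
#' @param model Fitted `ema_gbm`.
#' @param feature_names Optional override of the feature universe.
#' @return data.frame `feature`, `split_count`, `score`, `rank` (1 = most
#'   important; average ranks on ties), ordered by decreasing count.
#' @export
split_importance <- function(model, feature_names = model$feature_names) {
  tree <- xgboost::xgb.model.dt.tree(model = model$booster)
  tree <- as.data.frame(tree)
  splits <- tree$Feature[tree$Feature != "Leaf"]
  counts <- stats::setNames(rep(0L, length(feature_names)), feature_names)
  tab <- table(splits)
  counts[names(tab)] <- as.integer(tab)
  rng <- range(counts)
  score <- if (any(counts > 0)) {
    if (rng[2] > rng[1]) 100 * (counts - rng[1]) / (rng[2] - rng[1])
    else ifelse(counts > 0, 100, 0)
  } else rep(0, length(counts))
  out <- data.frame(feature = feature_names,
                    split_count = as.integer(counts),
                    score = as.numeric(score),
                    rank = rank(-counts, ties.method = "average"),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$split_count, out$feature), ]
  rownames(out) <- NULL
  out
}

#' Area under the ROC curve (Mann-Whitney)
#'
#' Probability that a random positive case receives a higher score than a
#' random negative case, ties counted 1/2.
#'
#' @param labels Binary 0/1 vector.
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in `[0,1]`.
#' @export
auc_mw <- function(labels, scores) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: one class absent", call. = FALSE)
  r <- rank(scores)                     # average ranks implement the tie-1/2 rule
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
}

#' Youden-optimal classification threshold
#'
#' Scans the observed scores as cut-points (positive = score >= threshold)
#' and returns the lowest threshold maximizing Youden's J
#' (sensitivity + specificity - 1).
#'
#' @inheritParams auc_mw
#' @return Named list `threshold`, `j`.
#' @export
youden_threshold <- function(labels, scores) {
  pos <- labels == 1
  if (!any(pos) || all(pos))
    stop("threshold undefined: one class absent", call. = FALSE)
  cuts <- sort(unique(scores))
  j <- vapply(cuts, function(t) {
    pred <- scores >= t
    sens <- sum(pred & pos) / sum(pos)
    spec <- sum(!pred & !pos) / sum(!pos)
    sens + spec - 1
  }, numeric(1))
  best <- which(j >= max(j) - 1e-12)[1]  # lowest cut among maximizers
  list(threshold = cuts[best], j = j[best])
}

#' Sensitivity, specificity and PPV at a threshold
#'
#' Standard 2x2-table definitions with "predicted positive" meaning
#' score >= threshold. PPV is `NA` (with a warning) when nothing is
#' predicted positive.
#'
#' @inheritParams auc_mw
#' @param threshold Classification cut-point.
#' @return Named numeric vector `sensitivity`, `specificity`, `ppv`.
#' @export
threshold_metrics <- function(labels, scores, threshold) {
  pos <- labels == 1
  if (!any(pos) || all(pos))
    stop("metrics undefined: one class absent", call. = FALSE)
  pred <- scores >= threshold
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  fn <- sum(!pred & pos); tn <- sum(!pred & !pos)
  ppv <- if (tp + fp == 0) {
    warning("no predicted positives; PPV undefined", call. = FALSE)
    NA_real_
  } else tp / (tp + fp)
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp), ppv = ppv)
}

#' Binomial proportion with a Wald 95% confidence interval
#'
#' Normal-approximation interval `p +/- 1.96 sqrt(p(1-p)/n)`, clipped to
#' `[0, 1]` and reported as percentages.
#'
#' @param labels Binary 0/1 vector (or use `x` and `n` directly).
#' @param x,n Optional count of positives and total, instead of `labels`.
#' @return Named numeric vector `percent`, `lower`, `upper` (percent scale).
#' @export
prevalence_with_ci <- function(labels = NULL, x = sum(labels), n = length(labels)) {
  if (n < 1) stop("prevalence undefined for empty sample", call. = FALSE)
  p <- x / n
  half <- 1.96 * sqrt(p * (1 - p) / n)
  c(percent = 100 * p,
    lower = 100 * max(0, p - half),
    upper = 100 * min(1, p + half))
}

#' Stratified cross-validation fold assignments
#'
#' Within each class, participants are shuffled and dealt round-robin into
#' `k` folds, so per-fold class counts differ from proportionality by at most
#' one participant.
#'
#' @param labels Binary 0/1 vector.
#' @param k Number of folds.
#' @param repetitions Number of independent repetitions.
#' @param seed Integer seed.
#' @return List of length `repetitions`; each element an integer fold id
#'   (1..k) per observation.
#' @export
make_folds <- function(labels, k, repetitions = 1L, seed = 1L) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  n <- length(labels)
  if (n < k) stop("fewer observations than folds", call. = FALSE)
  set.seed(as.integer(seed))
  lapply(seq_len(repetitions), function(r) {
    fold <- integer(n)
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Cross-validation scheme descriptor
#'
#' @param k Folds (ignored for LOOCV).
#' @param repetitions Repetitions (ignored for LOOCV).
#' @param variant `"kfold"` or `"loocv"`.
#' @param seed Integer seed used for fold construction.
#' @return List of class `cv_scheme`.
#' @export
cv_scheme <- function(k = 5L, repetitions = 3L, variant = c("kfold", "loocv"),
                      seed = 1L) {
  variant <- match.arg(variant)
  if (variant == "kfold" && k < 2) stop("k must be >= 2", call. = FALSE)
  if (repetitions < 1) stop("repetitions must be >= 1", call. = FALSE)
  structure(list(k = as.integer(k), repetitions = as.integer(repetitions),
                 variant = variant, seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Random-search hyperparameter tuning
#'
#' Samples `n_candidates` configurations from a small discrete space (number
#' of trees, learning rate, depth, minimum child weight, row/column
#' subsampling) and returns the one maximizing mean inner-CV AUC; ties are
#' broken by fewer trees, then shallower depth.
#'
#' @param x Feature table/matrix. @param y Binary labels.
#' @param n_candidates Number of sampled configurations.
#' @param inner_k Inner CV folds.
#' @param seed Integer seed.
#' @return Hyperparameter list as in [default_hyperparams()].
#' @export
tune_hyperparams <- function(x, y, n_candidates = 25L, inner_k = 3L, seed = 1L) {
  x <- as_feature_matrix(x)
  space <- list(nrounds = c(50L, 100L, 150L, 200L, 300L),
                eta = c(0.03, 0.05, 0.1, 0.2),
                max_depth = c(2L, 3L, 4L, 6L),
                min_child_weight = c(1, 3, 5, 10),
                subsample = c(0.6, 0.8, 1),
                colsample_bytree = c(0.6, 0.8, 1))
  set.seed(as.integer(seed))
  cand <- lapply(seq_len(n_candidates), function(i)
    lapply(space, function(v) sample(v, 1)))
  folds <- make_folds(y, inner_k, 1L, seed = seed + 1L)[[1]]
  score <- vapply(seq_along(cand), function(ci) {
    aucs <- vapply(seq_len(inner_k), function(f) {
      tr <- folds != f; te <- !tr
      if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 2) return(NA_real_)
      fit <- fit_gbm(x[tr, , drop = FALSE], y[tr], cand[[ci]], seed = seed)
      auc_mw(y[te], predict(fit, x[te, , drop = FALSE]))
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  if (all(is.na(score))) stop("degenerate inner folds", call. = FALSE)
  ord <- order(-score,
               vapply(cand, function(cc) cc$nrounds, numeric(1)),
               vapply(cand, function(cc) cc$max_depth, numeric(1)))
  cand[[ord[1]]]
}

#' Repeated stratified cross-validation of a GBM classifier
#'
#' For each repetition and fold: (optionally) tune hyperparameters on the
#' training portion, fit, pick the classification threshold on the training
#' predictions (Youden's J by default), and score the held-out portion with
#' AUC, sensitivity, specificity and PPV. Folds lacking a class are skipped
#' with a warning and recorded. Under `variant = "loocv"` all held-out
#' predictions are pooled first and one set of metrics is computed, with the
#' Youden threshold taken on the pooled out-of-sample scores.
#'
#' `x` may be a feature table/matrix, or a builder
#' `function(train_idx, test_idx)` returning `list(train = , test = )`
#' feature matrices — the hook the experiment drivers use to derive PAC
#' thresholds on training participants only.
#'
#' @param x Features or fold-wise feature builder (see Details).
#' @param labels Binary 0/1 outcome vector.
#' @param scheme A [cv_scheme()].
#' @param hyperparams Fixed hyperparameters ([default_hyperparams()]).
#' @param tuning `NULL` (default) or a list of arguments to
#'   [tune_hyperparams()] (e.g. `list(n_candidates = 25)`) applied per fold.
#' @param threshold_rule `"youden"` or `"fixed"` (0.5).
#' @param folds Optional precomputed fold list ([make_folds()]) so several
#'   designs share identical splits.
#' @return Object of class `metric_distribution`: `$folds` (per repetition x
#'   fold metric rows), `$summary` (mean and normal-approximation 95% CI per
#'   metric), `$skipped`, `$fold_assignments`.
#' @export
repeated_cv <- function(x, labels, scheme = cv_scheme(),
                        hyperparams = default_hyperparams(), tuning = NULL,
                        threshold_rule = c("youden", "fixed"), folds = NULL) {
  threshold_rule <- match.arg(threshold_rule)
  labels <- as.integer(labels)
  n <- length(labels)
  if (length(unique(labels)) < 2)
    stop("labels contain a single class", call. = FALSE)
  builder <- if (is.function(x)) x else {
    xm <- as_feature_matrix(x)
    if (nrow(xm) != n) stop("x and labels sizes differ", call. = FALSE)
    function(tr, te) list(train = xm[tr, , drop = FALSE],
                          test = xm[te, , drop = FALSE])
  }

  if (scheme$variant == "loocv") {
    scores <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      tr <- setdiff(seq_len(n), i)
      if (length(unique(labels[tr])) < 2) next
      mats <- builder(tr, i)
      fit <- fit_gbm(mats$train, labels[tr], hyperparams, seed = scheme$seed + i)
      scores[i] <- predict(fit, mats$test)
    }
    ok <- !is.na(scores)
    thr <- if (threshold_rule == "fixed") 0.5
           else youden_threshold(labels[ok], scores[ok])$threshold
    tm <- threshold_metrics(labels[ok], scores[ok], thr)
    row <- data.frame(repetition = 1L, fold = NA_integer_,
                      auc = auc_mw(labels[ok], scores[ok]),
                      sensitivity = tm[["sensitivity"]],
                      specificity = tm[["specificity"]],
                      ppv = tm[["ppv"]], threshold = thr)
    return(structure(list(folds = row,
                          summary = summarize_metric_rows(row),
                          skipped = integer(), fold_assignments = NULL,
                          scheme = scheme, pooled_scores = scores),
                     class = "metric_distribution"))
  }

  if (n < scheme$k) stop("fewer observations than folds", call. = FALSE)
  if (is.null(folds))
    folds <- make_folds(labels, scheme$k, scheme$repetitions, seed = scheme$seed)
  rows <- list(); skipped <- character()
  for (r in seq_along(folds)) {
    assign <- folds[[r]]
    for (f in sort(unique(assign))) {
      te <- which(assign == f); tr <- which(assign != f)
      if (length(unique(labels[tr])) < 2 || length(unique(labels[te])) < 2) {
        skipped <- c(skipped, sprintf("rep %d fold %d", r, f))
        next
      }
      mats <- builder(tr, te)
      hp <- hyperparams
      if (!is.null(tuning))
        hp <- do.call(tune_hyperparams,
                      c(list(x = mats$train, y = labels[tr],
                             seed = scheme$seed + 100L * r + f), tuning))
      fit <- fit_gbm(mats$train, labels[tr], hp,
                     seed = scheme$seed + 100L * r + f)
      thr <- if (threshold_rule == "fixed") 0.5 else
        youden_threshold(labels[tr], predict(fit, mats$train))$threshold
      sc <- predict(fit, mats$test)
      tm <- suppressWarnings(threshold_metrics(labels[te], sc, thr))
      rows[[length(rows) + 1L]] <-
        data.frame(repetition = r, fold = f, auc = auc_mw(labels[te], sc),
                   sensitivity = tm[["sensitivity"]],
                   specificity = tm[["specificity"]],
                   ppv = tm[["ppv"]], threshold = thr)
    }
  }
  if (length(skipped))
    warning(sprintf("skipped %d fold(s) lacking both classes: %s",
                    length(skipped), paste(skipped, collapse = "; ")),
            call. = FALSE)
  folds_df <- do.call(rbind, rows)
  structure(list(folds = folds_df, summary = summarize_metric_rows(folds_df),
                 skipped = skipped, fold_assignments = folds, scheme = scheme),
            class = "metric_distribution")
}

summarize_metric_rows <- function(rows) {
  metrics <- c("auc", "sensitivity", "specificity", "ppv")
  do.call(rbind, lapply(metrics, function(m) {
    v <- rows[[m]]; v <- v[!is.na(v)]
    mu <- mean(v)
    se <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    data.frame(metric = m, mean = mu,
               lower = if (is.na(se)) NA_real_ else max(0, mu - 1.96 * se),
               upper = if (is.na(se)) NA_real_ else min(1, mu + 1.96 * se),
               n = length(v), stringsAsFactors = FALSE)
  }))
}

#' @export
print.metric_distribution <- function(x, ...) {
  cat(sprintf("cross-validated metrics over %d fold evaluation(s)\n",
              nrow(x$folds)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-11s %.3f (95%% CI %.3f-%.3f)\n", s$metric[i], s$mean[i],
                s$lower[i], s$upper[i]))
  invisible(x)
}
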