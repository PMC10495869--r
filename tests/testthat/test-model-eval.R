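test_that("AUC matches the pairwise-enumeration oracle on random sets", {
  expect_equal(auc_mw(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)), 0.75)
  expect_equal(auc_mw(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1.0)
  expect_equal(auc_mw(c(0, 1, 0, 1), rep(0.4, 4)), 0.5)
  set.seed(3)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    labels <- c(0, 1, stats::rbinom(n - 2, 1, 0.4))   # both classes present
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
    expect_equal(auc_mw(labels, scores), oracle_auc(labels, scores),
                 tolerance = 1e-12)
  }
  expect_error(auc_mw(rep(1, 5), stats::runif(5)), "one class absent")
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(4)
  labels <- stats::rbinom(50, 1, 0.5)
  scores <- stats::rnorm(50)
  a <- auc_mw(labels, scores)
  expect_equal(auc_mw(labels, exp(scores)), a)
  expect_equal(auc_mw(labels, 3 * scores - 7), a)
  expect_equal(auc_mw(labels, stats::plogis(scores)), a)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  labels <- stats::rbinom(80, 1, 0.4)
  scores <- stats::rnorm(80) + labels
  expect_equal(auc_mw(labels, scores),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))))
})

test_that("Youden threshold maximizes J and is self-consistent", {
  labels <- c(0, 0, 0, 1, 1, 1)
  scores <- c(0.1, 0.2, 0.3, 0.71, 0.8, 0.9)
  yt <- youden_threshold(labels, scores)
  expect_equal(yt$threshold, 0.71)                 # lowest observed maximizer
  expect_equal(yt$j, 1)
  set.seed(6)
  for (i in 1:25) {
    labels <- c(0, 1, stats::rbinom(28, 1, 0.5))
    scores <- round(stats::runif(30), 2)
    yt <- youden_threshold(labels, scores)
    # exhaustive scan over all cuts agrees with returned J
    js <- vapply(sort(unique(scores)), function(t) {
      sens <- mean(scores[labels == 1] >= t)
      spec <- mean(scores[labels == 0] < t)
      sens + spec - 1
    }, numeric(1))
    expect_equal(yt$j, max(js), tolerance = 1e-12)
    m <- threshold_metrics(labels, scores, yt$threshold)
    expect_equal(m[["sensitivity"]] + m[["specificity"]] - 1, yt$j,
                 tolerance = 1e-12)
  }
})

test_that("threshold metrics reproduce the 2x2 table", {
  m <- threshold_metrics(c(1, 1, 0, 0), c(0.9, 0.2, 0.8, 0.1), 0.5)
  expect_equal(unname(m), c(0.5, 0.5, 0.5))
  perfect <- threshold_metrics(c(1, 0), c(0.9, 0.1), 0.5)
  expect_equal(unname(perfect), c(1, 1, 1))
  expect_warning(m2 <- threshold_metrics(c(1, 0), c(0.4, 0.3), 0.9),
                 "no predicted positives")
  expect_true(is.na(m2[["ppv"]]))
})

test_that("Wald prevalence interval reproduces printed cohort bounds", {
  ci1 <- prevalence_with_ci(x = 19, n = 103)
  expect_equal(round(ci1[["percent"]], 1), 18.4)
  # the printed 10.9 arises from the pre-rounded 18.4%; exact p gives 10.96
  expect_equal(ci1[["lower"]], 10.9, tolerance = 0.01)
  expect_equal(round(ci1[["upper"]], 1), 25.9)
  ci2 <- prevalence_with_ci(x = 32, n = 103)
  expect_equal(round(ci2[["upper"]], 1), 40.0)
  expect_equal(unname(prevalence_with_ci(rep(0, 100))), c(0, 0, 0))
  expect_error(prevalence_with_ci(integer()), "empty")
})

test_that("classifier separates a separable toy problem and is deterministic", {
  set.seed(7)
  x <- matrix(stats::rnorm(200 * 2), 200)
  y <- as.integer(x[, 1] > 0)
  fit <- fit_gbm(x, y, seed = 5)
  expect_equal(auc_mw(y, predict(fit, x)), 1.0)
  fit2 <- fit_gbm(x, y, seed = 5)
  expect_identical(predict(fit, x), predict(fit2, x))
  expect_error(fit_gbm(x, rep(1, 200)), "single class")
})

test_that("split importance scales counts to 0-100 and preserves ranking", {
  set.seed(8)
  x <- matrix(stats::rnorm(300 * 5), 300,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- as.integer(x[, 1] + 0.3 * x[, 2] + stats::rnorm(300, 0, 0.5) > 0)
  fit <- fit_gbm(x, y, seed = 9)
  imp <- split_importance(fit)
  expect_equal(max(imp$score), 100)
  expect_equal(imp$feature[1], "f1")
  expect_true(all(imp$score >= 0 & imp$score <= 100))
  expect_equal(order(-imp$split_count), order(-imp$score))
  # totals equal the ensemble's split count
  tree <- as.data.frame(xgboost::xgb.model.dt.tree(model = fit$booster))
  expect_equal(sum(imp$split_count), sum(tree$Feature != "Leaf"))
  # min-max arithmetic on a known vector
  counts <- c(10, 5, 0)
  expect_equal(100 * (counts - min(counts)) / diff(range(counts)),
               c(100, 50, 0))
})

test_that("stratified folds balance classes to within one participant", {
  set.seed(10)
  labels <- stats::rbinom(103, 1, 0.25)
  folds <- make_folds(labels, k = 5, repetitions = 3, seed = 2)
  expect_length(folds, 3)
  for (assign in folds) {
    expect_setequal(unique(assign), 1:5)
    pos_per_fold <- vapply(1:5, function(f) sum(labels[assign == f]),
                           numeric(1))
    expect_lte(diff(range(pos_per_fold)), 1)
    n_per_fold <- tabulate(assign, 5)
    expect_lte(diff(range(n_per_fold)), 2)       # one per class at most
  }
})

test_that("repeated CV yields k x repetitions fold rows and is reproducible", {
  co <- tiny_cohort(n = 103, seed = 15, missing_rate = 0.055)
  daily <- cohort_daily(co)
  md <- ema_design_cv(daily, co$outcomes, "1mo",
                      scheme = cv_scheme(5, 3, seed = 77))
  expect_equal(nrow(md$folds), 15)
  expect_true(all(md$folds$auc >= 0 & md$folds$auc <= 1))
  s <- md$summary
  expect_true(all(s$lower <= s$mean & s$mean <= s$upper, na.rm = TRUE))
  md2 <- ema_design_cv(daily, co$outcomes, "1mo",
                       scheme = cv_scheme(5, 3, seed = 77))
  expect_identical(md$folds, md2$folds)
})

test_that("null features give chance-level out-of-fold AUC", {
  set.seed(11)
  x <- matrix(stats::rnorm(500 * 10), 500)
  y <- stats::rbinom(500, 1, 0.5)
  md <- repeated_cv(x, y, scheme = cv_scheme(5, 2, seed = 3))
  expect_gt(md$summary$mean[md$summary$metric == "auc"], 0.40)
  expect_lt(md$summary$mean[md$summary$metric == "auc"], 0.60)
})

test_that("LOOCV pools held-out predictions into a single metric row", {
  set.seed(12)
  x <- matrix(stats::rnorm(24 * 3), 24)
  x[, 1] <- x[, 1] + 2 * rep(0:1, each = 12)
  y <- rep(0:1, each = 12)
  # small-sample settings: the default min_child_weight forbids any split
  # at n = 23, collapsing the model to its (inverted) deleted-case base rate
  md <- repeated_cv(x, y, scheme = cv_scheme(variant = "loocv", seed = 4),
                    hyperparams = list(min_child_weight = 1, nrounds = 50L))
  expect_equal(nrow(md$folds), 1)
  expect_length(md$pooled_scores, 24)
  expect_gt(md$folds$auc, 0.8)
})

test_that("hyperparameter tuning returns the candidate and is deterministic", {
  set.seed(13)
  x <- matrix(stats::rnorm(150 * 4), 150)
  y <- as.integer(x[, 1] + stats::rnorm(150, 0, 0.7) > 0)
  a <- tune_hyperparams(x, y, n_candidates = 4, seed = 21)
  b <- tune_hyperparams(x, y, n_candidates = 4, seed = 21)
  expect_identical(a, b)
  expect_named(a, c("nrounds", "eta", "max_depth", "min_child_weight",
                    "subsample", "colsample_bytree"))
})
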