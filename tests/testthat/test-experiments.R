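test_that("Welch t matches the closed-form computation and is antisymmetric", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  got <- welch_t(a, b)
  se <- sqrt(stats::var(a) / 3 + stats::var(b) / 3)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((stats::var(a) / 3)^2 / 2 + (stats::var(b) / 3)^2 / 2)
  expect_equal(got$t, t_hand, tolerance = 1e-12)
  expect_equal(got$df, df_hand, tolerance = 1e-12)
  expect_equal(got$p, 2 * stats::pt(-abs(t_hand), df_hand), tolerance = 1e-12)
  swapped <- welch_t(b, a)
  expect_equal(swapped$t, -got$t)
  expect_equal(swapped$p, got$p)
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
  expect_error(welch_t(c(1, 1, 1), c(1, 1, 1)), "constant")
})

test_that("BH adjustment matches the hand step-up on all small subsets", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  pool <- c(0.001, 0.011, 0.039, 0.041, 0.2, 0.49, 0.74, 1)
  for (size in 1:5) {
    combos <- utils::combn(length(pool), size, simplify = FALSE)
    for (idx in combos) {
      p <- pool[idx]
      expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    }
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("BH output is monotone and never below raw p", {
  set.seed(20)
  for (i in 1:50) {
    p <- stats::runif(sample(2:12, 1))
    adj <- bh_adjust(p)
    expect_true(all(adj >= p - 1e-12))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
  }
})

test_that("predictor-set comparison shares folds and adjusts 12 p-values", {
  co <- tiny_cohort(n = 80, seed = 31, missing_rate = 0.055)
  daily <- cohort_daily(co)
  ex <- compare_predictor_sets(daily, co$baselines, co$outcomes, "1mo",
                               scheme = cv_scheme(4, 2, seed = 5))
  expect_setequal(names(ex$results), c("baseline", "ema", "baseline_plus_ema"))
  expect_equal(nrow(ex$tests), 12)              # 3 pairs x 4 metrics
  ok <- !is.na(ex$tests$p)
  expect_true(all(ex$tests$p_adj[ok] >= ex$tests$p[ok] - 1e-12))
  # shared folds: every design evaluated the same rows
  expect_identical(ex$results$baseline$fold_assignments,
                   ex$results$ema$fold_assignments)
})

test_that("identical designs give t near 0 and p near 1", {
  set.seed(21)
  rows <- data.frame(repetition = rep(1:3, each = 5), fold = rep(1:5, 3),
                     auc = stats::runif(15, 0.6, 0.8))
  rows$sensitivity <- rows$specificity <- rows$ppv <- rows$auc
  fake <- list(a = list(folds = rows), b = list(folds = rows))
  tests <- emarisk:::pairwise_metric_tests(fake)
  expect_true(all(abs(tests$t) < 1e-8))
  expect_true(all(tests$p > 0.999))
})

test_that("EMA-only signal puts the EMA design ahead of baseline", {
  # EMA features carry the outcome signal; baseline history does not
  co <- simulate_cohort(sim_config(n_participants = 250,
                                   beta_baseline_si = 0, seed = 33))
  daily <- cohort_daily(co)
  ex <- compare_predictor_sets(daily, co$baselines, co$outcomes, "1mo",
                               scheme = cv_scheme(5, 2, seed = 6))
  auc_of <- function(d)
    ex$results[[d]]$summary$mean[ex$results[[d]]$summary$metric == "auc"]
  expect_gt(auc_of("ema"), auc_of("baseline") + 0.1)
})

test_that("day curve: k = n_days equals the full-window analysis", {
  co <- tiny_cohort(n = 60, seed = 34, missing_rate = 0.055)
  daily <- cohort_daily(co)
  sch <- cv_scheme(4, 1, seed = 8)
  dc <- incremental_day_curve(daily, co$outcomes, "1mo", scheme = sch,
                              k_range = c(5, 25))
  full <- ema_design_cv(daily, co$outcomes, "1mo", scheme = sch)
  expect_equal(dc$results[["days_1..25"]]$folds, full$folds)
  expect_equal(dc$curve$mean_auc[dc$curve$k == 25],
               full$summary$mean[full$summary$metric == "auc"])
})

test_that("day curve reports the first threshold crossing", {
  curve_from <- function(aucs, ks = seq_along(aucs)) {
    # exercise the crossing rule directly on a synthetic curve
    crossing <- ks[aucs > 0.7]
    if (length(crossing)) min(crossing) else NA_integer_
  }
  expect_equal(curve_from(c(0.5, 0.65, 0.72, 0.71)), 3)
  expect_true(is.na(curve_from(c(0.5, 0.6))))
  co <- tiny_cohort(n = 60, seed = 35)
  daily <- cohort_daily(co)
  dc <- incremental_day_curve(daily, co$outcomes, "1mo",
                              scheme = cv_scheme(4, 1, seed = 9),
                              k_range = c(2, 25))
  expect_true(is.na(dc$crossing_k) ||
                dc$curve$mean_auc[match(dc$crossing_k, dc$curve$k)] > 0.7)
})

test_that("wave analysis partitions days per the boundaries", {
  wd <- wave_days(25, c(8, 17))
  expect_equal(wd$wave1, 1:8)
  expect_equal(wd$wave2, 9:17)
  expect_equal(wd$wave3, 18:25)
  expect_equal(sort(unlist(wd)), 1:25, ignore_attr = TRUE)

  co <- tiny_cohort(n = 60, seed = 36, missing_rate = 0.055)
  daily <- cohort_daily(co)
  wa <- wave_analysis(daily, co$outcomes, "1mo",
                      scheme = cv_scheme(4, 1, seed = 10))
  expect_setequal(names(wa$results), c("wave1", "wave2", "wave3"))
  expect_equal(nrow(wa$tests), 12)
  expect_error(wave_analysis(daily, co$outcomes, "1mo",
                             wave_boundaries = c(24, 25)),
               "wave")
})
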