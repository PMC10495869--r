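test_that("summaries of simple series match hand values", {
  s <- series_summaries(c(3, 3, 3, 3), 1:4, pac_threshold = 2)
  expect_equal(unname(s), c(3, 0, 0, 0, 0))

  expect_equal(series_summaries(c(1, 2, 3), 1:3, 1)[["slope"]], 1.0)

  s <- series_summaries(c(0, 6, 0, 6), 1:4, pac_threshold = 3)
  expect_equal(s[["max_change"]], 6)
  expect_equal(s[["pac"]], 1.0)
  o <- oracle_summaries(c(0, 6, 0, 6), 1:4)
  expect_equal(s[["sd"]], o$sd)
  expect_equal(s[["slope"]], o$slope)
})

test_that("summaries match a brute-force oracle on 1000 random series", {
  set.seed(1)
  for (i in 1:1000) {
    n <- sample(2:25, 1)
    days <- sort(sample(1:25, n))
    vals <- round(stats::runif(n, 0, 6), 2)
    if (stats::sd(vals) == 0) vals[1] <- vals[1] + 1
    thr <- stats::runif(1, 0.5, 3)
    got <- series_summaries(vals, days, thr)
    o <- oracle_summaries(vals, days)
    expect_equal(got[["mean"]], o$mean, tolerance = 1e-10)
    expect_equal(got[["sd"]], o$sd, tolerance = 1e-10)
    expect_equal(got[["slope"]], o$slope, tolerance = 1e-10)
    expect_equal(got[["max_change"]], o$max_change, tolerance = 1e-10)
    expect_equal(got[["pac"]], mean(abs(diff(vals)) >= thr), tolerance = 1e-10)
  }
})

test_that("summaries respect shift invariances and degenerate input rules", {
  set.seed(2)
  vals <- stats::runif(10, 0, 6); days <- sort(sample(1:25, 10))
  a <- series_summaries(vals, days, 1)
  b <- series_summaries(vals + 100, days, 1)
  expect_equal(a[["sd"]], b[["sd"]])
  expect_equal(a[["slope"]], b[["slope"]], tolerance = 1e-9)
  expect_equal(a[["pac"]], b[["pac"]])
  expect_error(series_summaries(numeric(), integer(), 1), "empty")
  expect_error(series_summaries(c(1, 2), c(2, 1), 1), "increasing")
  one <- series_summaries(5, 3, 1)
  expect_equal(unname(one), c(5, 0, 0, 0, 0))
})

test_that("PAC threshold is the interpolated 90th percentile of pooled diffs", {
  expect_equal(default_pac_threshold(rep(2, 50)), 2)
  expect_equal(default_pac_threshold(0:10), 9.0)
  expect_equal(default_pac_threshold(3.7), 3.7)      # single pair
  expect_error(default_pac_threshold(numeric()), "no successive differences")
})

test_that("event frequencies count endorsement days and most-stressful days", {
  rows <- lapply(1:6, function(d) {
    r <- survey_row("P1", d, "morning",
                    events = "marriage", most_stressful = "marriage",
                    worry = 3L)
    e <- survey_row("P1", d, "evening")
    if (d <= 2) {                                     # economy tops 2 days
      e$events <- "marriage;economy"; e$most_stressful <- "economy"
      e$worry <- 5L
    }
    rbind(r, e)
  })
  ds <- ema_dataset(do.call(rbind, rows), participants = "P1")
  daily <- day_aggregate(ds)
  f <- event_frequencies(daily)
  expect_equal(unname(f["freq_marriage"]), 6)
  expect_equal(unname(f["ms_freq_marriage"]), 4)
  expect_equal(unname(f["ms_freq_economy"]), 2)
  expect_equal(unname(f["freq_economy"]), 2)
  expect_equal(sum(f), 6 + 4 + 2 + 2)
  # windowing drops out-of-window days
  f3 <- event_frequencies(daily, window = 1:3)
  expect_equal(unname(f3["freq_marriage"]), 3)
  # no events at all
  empty <- day_aggregate(ema_dataset(survey_row("P2", 1, "morning"),
                                     participants = "P2"),
                         require_both = FALSE)
  expect_true(all(event_frequencies(empty) == 0))
})

test_that("feature table has exactly 60 EMA columns for any window or wave", {
  co <- tiny_cohort(n = 12, seed = 6, missing_rate = 0.1)
  daily <- cohort_daily(co)
  ids <- co$baselines$participant_id
  for (win in list(NULL, 1:10, wave_days(25, c(8, 17))$wave2, 1)) {
    ft <- suppressWarnings(
      build_feature_table(daily, ids, window = win,
                          thresholds = stats::setNames(
                            rep(1, 8), dynamic_series_names())))
    expect_identical(setdiff(names(ft), "participant_id"), ema_feature_names())
    expect_equal(nrow(ft), 12)
    expect_false(anyNA(ft))
  }
})

test_that("wave windows cover only their own days", {
  co <- tiny_cohort(n = 6, seed = 9)
  daily <- cohort_daily(co)
  ids <- co$baselines$participant_id
  w2 <- wave_days(25, c(8, 17))$wave2
  manual <- daily[daily$day %in% w2, ]
  ft <- build_feature_table(daily, ids, window = w2)
  p1 <- ids[1]
  d1 <- manual[manual$participant_id == p1, ]
  expect_equal(ft$mood_content_mean[1], mean(d1$mood_content))
  expect_equal(ft$freq_marriage[1], sum(d1$ev_marriage))
})

test_that("permuting participant order permutes rows only", {
  co <- tiny_cohort(n = 10, seed = 14)
  daily <- cohort_daily(co)
  ids <- co$baselines$participant_id
  thr <- pac_thresholds(daily)
  a <- build_feature_table(daily, ids, thresholds = thr)
  b <- build_feature_table(daily, rev(ids), thresholds = thr)
  expect_equal(b[match(a$participant_id, b$participant_id), ], a,
               ignore_attr = TRUE)
})

test_that("baseline encoding follows the fixed codebook", {
  bl <- data.frame(participant_id = c("A", "B"),
                   baseline_si = c(0, 1),
                   nssi_freq_band = c("11-50", "0"),
                   lifetime_attempt = c(0, 0),
                   psych_dx_history = c(1, 0),
                   psych_tx_history = c(0, 0),
                   family_attempt_history = c(0, 1),
                   family_dx_history = c(0, 0))
  enc <- encode_baseline(bl)
  expect_equal(enc$nssi_freq_band, c(2, 0))
  expect_equal(ncol(enc), 8)                 # id + 7 predictors
  expect_true(all(enc$baseline_si %in% 0:1))
  expect_error(encode_baseline(transform(bl, nssi_freq_band = "lots")),
               "nssi_freq_band")
  expect_error(encode_baseline(rbind(bl, bl)), "duplicate")
})
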