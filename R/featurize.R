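#' Five summaries of an intensive-longitudinal series
#'
#' Computes the standard within-person dynamics summaries of a day-level
#' series: arithmetic mean, sample SD (n-1 denominator), ordinary
#' least-squares slope of the values on the (possibly gapped) day indices,
#' maximum absolute successive change, and the probability of acute change
#' (PAC): the fraction of successive changes whose absolute value is at least
#' `pac_threshold`. Successive differences are taken between adjacent
#' *retained* days, skipping across dropped days.
#'
#' With a single observation the mean is defined and sd/slope/max_change/pac
#' fall back to 0 (the degenerate-window policy; see the package vignette).
#'
#' @param values Numeric series.
#' @param day_index Strictly increasing integer day indices, same length.
#' @param pac_threshold Positive acute-change cutoff, in the series' units.
#' @return Named numeric vector `mean`, `sd`, `slope`, `max_change`, `pac`.
#' @export
series_summaries <- function(values, day_index, pac_threshold) {
  n <- length(values)
  if (n == 0) stop("empty series", call. = FALSE)
  if (length(day_index) != n) stop("values and day_index lengths differ", call. = FALSE)
  if (n > 1 && any(diff(day_index) <= 0))
    stop("day_index must be strictly increasing", call. = FALSE)
  if (pac_threshold <= 0) stop("pac_threshold must be positive", call. = FALSE)
  m <- mean(values)
  if (n == 1)
    return(c(mean = m, sd = 0, slope = 0, max_change = 0, pac = 0))
  dx <- day_index - mean(day_index)
  slope <- sum(dx * (values - m)) / sum(dx^2)
  jumps <- abs(diff(values))
  c(mean = m, sd = stats::sd(values), slope = slope,
    max_change = max(jumps), pac = mean(jumps >= pac_threshold))
}

#' Default probability-of-acute-change thresholds
#'
#' For each dynamic series, the acute-change cutoff is the 90th percentile
#' (linear-interpolation, type 7) of the pooled absolute successive
#' differences across participants' retained days. Fit this on training
#' participants only and reuse the result on held-out participants to avoid
#' leakage; [repeated_cv()] and the experiment drivers do so automatically.
#'
#' @param daily Day-level data.frame from [day_aggregate()].
#' @param vars Series to compute thresholds for (default: the six mood items
#'   plus `event_count` and `most_stressful_level`).
#' @param window Optional day subset.
#' @param on_empty What to do when a series has no successive differences in
#'   the window (e.g. a single-day window): `"error"` (default) or `"inf"`,
#'   which returns `Inf` so that PAC degenerates to 0.
#' @return Named numeric vector of thresholds.
#' @export
pac_thresholds <- function(daily, vars = dynamic_series_names(), window = NULL,
                           on_empty = c("error", "inf")) {
  on_empty <- match.arg(on_empty)
  if (!is.null(window)) daily <- daily[daily$day %in% window, , drop = FALSE]
  sp <- split(daily, daily$participant_id)
  out <- vapply(vars, function(v) {
    diffs <- unlist(lapply(sp, function(d) {
      if (nrow(d) < 2) return(numeric())
      abs(diff(d[[v]][order(d$day)]))
    }), use.names = FALSE)
    if (!length(diffs)) {
      if (on_empty == "error")
        stop(sprintf("no successive differences available for '%s'", v),
             call. = FALSE)
      return(Inf)
    }
    stats::quantile(diffs, 0.9, names = FALSE, type = 7)
  }, numeric(1))
  out
}

#' @rdname pac_thresholds
#' @param abs_diffs Pooled absolute successive differences of one series.
#' @export
default_pac_threshold <- function(abs_diffs) {
  if (!length(abs_diffs)) stop("no successive differences", call. = FALSE)
  stats::quantile(abs_diffs, 0.9, names = FALSE, type = 7)
}

#' Per-category stressful-event frequencies
#'
#' Counts, for each of the ten categories, (a) the number of retained days in
#' the window on which the category was endorsed and (b) the number on which
#' it was the day's most-stressful selection.
#'
#' @param daily One participant's day-level rows.
#' @param window Day subset (default: all retained days).
#' @return Named integer vector of 20 counts, `freq_<cat>` then `ms_freq_<cat>`.
#' @export
event_frequencies <- function(daily, window = NULL) {
  if (!is.null(window)) daily <- daily[daily$day %in% window, , drop = FALSE]
  cats <- event_categories()
  ev <- vapply(paste0("ev_", cats), function(cc)
    if (nrow(daily)) sum(daily[[cc]]) else 0L, numeric(1))
  ms <- vapply(paste0("ms_", cats), function(cc)
    if (nrow(daily)) sum(daily[[cc]]) else 0L, numeric(1))
  stats::setNames(c(ev, ms), c(paste0("freq_", cats), paste0("ms_freq_", cats)))
}

#' Names of the 60 EMA feature columns, in canonical order
#' @return Character vector of length 60.
#' @export
ema_feature_names <- function() {
  dyn <- as.vector(vapply(dynamic_series_names(), function(v)
    paste(v, c("mean", "sd", "slope", "max_change", "pac"), sep = "_"),
    character(5)))
  c(dyn, paste0("freq_", event_categories()),
    paste0("ms_freq_", event_categories()))
}

#' Build the participants x 60 EMA feature table
#'
#' For every participant: the five dynamics summaries ([series_summaries()])
#' of each of the eight day-level series (six mood items, daily stressful
#' event count, daily most-stressful level) computed on the retained days in
#' the window (40 features), plus the 20 per-category event frequencies
#' ([event_frequencies()]). Participants with fewer than two retained days in
#' the window receive 0 for sd/slope/max_change/pac; a participant with no
#' retained days gets an all-zero row and a warning. The column set and order
#' are fixed ([ema_feature_names()]) regardless of missingness.
#'
#' @param daily Day-level data.frame from [day_aggregate()].
#' @param participants Participant IDs to emit rows for (default: those
#'   present in `daily`); order defines row order.
#' @param window Optional vector of day indices (e.g. `1:k` or a wave).
#' @param thresholds Named PAC thresholds from [pac_thresholds()]; computed
#'   from `daily` itself when omitted (fine for exploration, leaky inside
#'   cross-validation — the CV drivers pass training-fold thresholds).
#' @return data.frame with `participant_id` plus 60 numeric columns.
#' @export
build_feature_table <- function(daily, participants = NULL, window = NULL,
                                thresholds = NULL) {
  if (is.null(participants)) participants <- unique(daily$participant_id)
  if (!length(participants)) stop("empty cohort", call. = FALSE)
  if (!is.null(window)) daily <- daily[daily$day %in% window, , drop = FALSE]
  if (is.null(thresholds)) thresholds <- pac_thresholds(daily)
  thresholds <- pmax(thresholds, .Machine$double.eps)  # guard all-constant series
  vars <- dynamic_series_names()
  sp <- split(daily, factor(daily$participant_id, levels = participants))
  n_zero <- 0L
  rows <- lapply(participants, function(p) {
    d <- sp[[p]]
    if (is.null(d) || nrow(d) == 0) {
      n_zero <<- n_zero + 1L
      return(stats::setNames(rep(0, 60), ema_feature_names()))
    }
    d <- d[order(d$day), , drop = FALSE]
    dyn <- unlist(lapply(vars, function(v)
      stats::setNames(series_summaries(d[[v]], d$day, thresholds[[v]]),
                      paste(v, c("mean", "sd", "slope", "max_change", "pac"),
                            sep = "_"))))
    c(dyn, event_frequencies(d))
  })
  if (n_zero > 0)
    warning(sprintf("%d participant(s) with no retained days in window; all-zero rows emitted",
                    n_zero), call. = FALSE)
  ft <- as.data.frame(do.call(rbind, rows))
  ft <- ft[, ema_feature_names()]
  cbind(data.frame(participant_id = as.character(participants),
                   stringsAsFactors = FALSE), ft)
}

#' Encode the seven baseline predictors numerically
#'
#' Binary history fields pass through as 0/1; the lifetime NSSI frequency
#' band is coded ordinally (0 = none, 1 = 1-10, 2 = 11-50, 3 = >=51).
#'
#' @param baselines Baseline data.frame (one row per participant).
#' @return data.frame with `participant_id` plus 7 numeric columns.
#' @export
encode_baseline <- function(baselines) {
  if (anyDuplicated(baselines$participant_id))
    stop("duplicate participant in baseline records", call. = FALSE)
  band <- match(as.character(baselines$nssi_freq_band), nssi_band_levels()) - 1L
  if (anyNA(band))
    stop(sprintf("unknown nssi_freq_band label '%s'",
                 baselines$nssi_freq_band[which(is.na(band))[1]]), call. = FALSE)
  out <- baselines[, c("participant_id", baseline_predictors())]
  out$nssi_freq_band <- band
  for (col in setdiff(baseline_predictors(), "nssi_freq_band"))
    out[[col]] <- as.numeric(out[[col]])
  rownames(out) <- NULL
  out
}
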