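#' Construct an EMA dataset container
#'
#' Wraps a validated long survey table together with the full participant set
#' and the nominal schedule, so that compliance can be computed even for
#' participants with zero completed surveys.
#'
#' @param surveys Long survey data.frame (see [read_ema_long()] for columns).
#' @param participants Character vector of all enrolled participant IDs;
#'   defaults to the IDs present in `surveys`.
#' @param n_days Scheduled study length in days.
#' @param prompts_per_day Scheduled prompts per day.
#' @return List of class `ema_dataset`.
#' @export
ema_dataset <- function(surveys, participants = unique(surveys$participant_id),
                        n_days = 25L, prompts_per_day = 2L) {
  key <- paste(surveys$participant_id, surveys$day, surveys$slot)
  if (anyDuplicated(key))
    stop(sprintf("duplicate (participant, day, slot): %s",
                 key[which(duplicated(key))[1]]), call. = FALSE)
  if (nrow(surveys) && (min(surveys$day) < 1 || max(surveys$day) > n_days))
    stop(sprintf("day index outside 1..%d", n_days), call. = FALSE)
  structure(list(surveys = surveys, participants = as.character(participants),
                 n_days = as.integer(n_days),
                 prompts_per_day = as.integer(prompts_per_day)),
            class = "ema_dataset")
}

#' Read a long-format EMA survey CSV
#'
#' Expects the exact header
#' `participant_id,day,slot,mood_tired_awake,mood_content,mood_agitated_calm,`
#' `mood_energy,mood_ill_well,mood_relaxed_tense,events,most_stressful,worry`.
#' `events` is a semicolon-joined subset of [event_categories()] (empty =
#' none); `most_stressful` must be one of the endorsed categories (empty when
#' no event); `worry` is an integer 0-6, present exactly when an event was
#' endorsed. Malformed rows are rejected with their file line number.
#'
#' @param path CSV file path.
#' @param n_days Scheduled study length.
#' @param prompts_per_day Scheduled prompts per day.
#' @param participants Optional full enrollment list (defaults to IDs seen).
#' @return An [ema_dataset()].
#' @export
read_ema_long <- function(path, n_days = 25L, prompts_per_day = 2L,
                          participants = NULL) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(df), ema_csv_header()))
    stop(sprintf("unexpected EMA CSV header in %s", path), call. = FALSE)
  line <- seq_len(nrow(df)) + 1L   # header is line 1

  bad_line <- function(i, msg)
    stop(sprintf("%s: line %d: %s", path, line[i][1], msg), call. = FALSE)

  day <- suppressWarnings(as.integer(df$day))
  if (anyNA(day)) bad_line(which(is.na(day)), "non-integer 'day'")
  if (any(day < 1 | day > n_days))
    bad_line(which(day < 1 | day > n_days),
             sprintf("'day' outside 1..%d", n_days))
  if (!all(df$slot %in% prompt_slots()))
    bad_line(which(!df$slot %in% prompt_slots()),
             "'slot' must be morning or evening")

  for (m in mood_items()) {
    v <- suppressWarnings(as.integer(df[[m]]))
    if (anyNA(v)) bad_line(which(is.na(v)), sprintf("non-integer '%s'", m))
    if (any(v < 0 | v > 6))
      bad_line(which(v < 0 | v > 6), sprintf("'%s' outside 0..6", m))
    df[[m]] <- v
  }

  ev_list <- strsplit(df$events, ";", fixed = TRUE)
  cats <- event_categories()
  for (i in seq_along(ev_list)) {
    ev <- ev_list[[i]]
    unknown <- setdiff(ev, cats)
    if (length(unknown))
      bad_line(i, sprintf("unknown event category '%s'", unknown[1]))
    if (anyDuplicated(ev)) bad_line(i, "duplicated event category")
    ms <- df$most_stressful[i]
    if (length(ev) == 0) {
      if (nzchar(ms)) bad_line(i, "'most_stressful' given without events")
      if (nzchar(df$worry[i])) bad_line(i, "'worry' given without events")
    } else {
      if (!ms %in% ev)
        bad_line(i, "'most_stressful' not among endorsed events")
      w <- suppressWarnings(as.integer(df$worry[i]))
      if (is.na(w) || w < 0 || w > 6)
        bad_line(i, "'worry' must be an integer 0..6 when events are endorsed")
    }
  }
  df$worry <- suppressWarnings(as.integer(df$worry))
  df$day <- day

  ds <- ema_dataset(df, participants = participants %||% unique(df$participant_id),
                    n_days = n_days, prompts_per_day = prompts_per_day)
  ds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write surveys to the canonical EMA CSV
#' @param surveys Long survey data.frame (as produced by [simulate_cohort()]).
#' @param path Output file.
#' @export
write_ema_csv <- function(surveys, path) {
  df <- surveys[, ema_csv_header()]
  df$worry[is.na(df$worry)] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write the participant baseline table
#'
#' One row per participant: the 7 baseline predictors plus the four
#' suicidal-ideation outcome columns (`si_baseline`, `si_1mo`, `si_3mo`,
#' `si_8mo`).
#'
#' @param path CSV file path.
#' @return For `read_baseline_csv`, a list with data.frames `baselines` and
#'   `outcomes`.
#' @export
read_baseline_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("participant_id", baseline_predictors(),
            paste0("si_", outcome_horizons()))
  if (!identical(names(df), need))
    stop(sprintf("unexpected baseline CSV header in %s", path), call. = FALSE)
  if (anyDuplicated(df$participant_id))
    stop("duplicate participant_id in baseline file", call. = FALSE)
  for (col in setdiff(need, c("participant_id", "nssi_freq_band"))) {
    v <- suppressWarnings(as.integer(df[[col]]))
    if (anyNA(v) || any(!v %in% 0:1))
      stop(sprintf("column '%s' must be binary 0/1", col), call. = FALSE)
    df[[col]] <- v
  }
  if (!all(df$nssi_freq_band %in% nssi_band_levels()))
    stop("unknown nssi_freq_band label", call. = FALSE)
  outcomes <- data.frame(participant_id = df$participant_id,
                         si_baseline = df$baseline_si,
                         stringsAsFactors = FALSE)
  outcomes[paste0("si_", outcome_horizons())] <-
    df[paste0("si_", outcome_horizons())]
  list(baselines = df[, c("participant_id", baseline_predictors())],
       outcomes = outcomes)
}

#' @rdname read_baseline_csv
#' @param baselines Baseline predictor data.frame.
#' @param outcomes Outcome label data.frame.
#' @export
write_baseline_csv <- function(baselines, outcomes, path) {
  df <- merge(baselines, outcomes[, setdiff(names(outcomes), "si_baseline")],
              by = "participant_id", sort = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Compliance rate of an EMA dataset
#'
#' Completed surveys divided by scheduled surveys
#' (participants x days x prompts per day).
#'
#' @param ds An [ema_dataset()].
#' @return Fraction in `[0,1]`.
#' @export
compliance_rate <- function(ds) {
  stopifnot(inherits(ds, "ema_dataset"))
  expected <- length(ds$participants) * ds$n_days * ds$prompts_per_day
  if (expected == 0)
    stop("compliance rate undefined: zero expected surveys", call. = FALSE)
  nrow(ds$surveys) / expected
}

#' Aggregate prompt-level surveys to day-level series
#'
#' A day is retained for a participant only when responses are available for
#' that day (by default both scheduled prompts; set `require_both = FALSE` to
#' keep days with at least one prompt). Retained days carry: the mean of the
#' available prompts for each mood item, the number of distinct event
#' categories endorsed that day (union over prompts), the day's maximum worry
#' rating (`most_stressful_level`, 0 when no event), per-category endorsement
#' flags `ev_<category>`, and one-hot flags `ms_<category>` for the day's
#' most-stressful selection (taken from the prompt with the highest worry;
#' prompt order breaks ties).
#'
#' @param ds An [ema_dataset()].
#' @param require_both If `TRUE` (default) a day with any missing scheduled
#'   prompt is dropped entirely.
#' @return Day-level data.frame, one row per retained participant-day,
#'   ordered by participant then day.
#' @export
day_aggregate <- function(ds, require_both = TRUE) {
  stopifnot(inherits(ds, "ema_dataset"))
  s <- ds$surveys
  cats <- event_categories()
  if (!nrow(s))
    return(data.frame(participant_id = character(), day = integer()))

  # order prompts morning-first within day so ties break deterministically
  s <- s[order(s$participant_id, s$day, match(s$slot, prompt_slots())), ]
  ki <- cumsum(!duplicated(paste(s$participant_id, s$day)))  # group index, ordered
  n_g <- ki[length(ki)]
  counts <- tabulate(ki, n_g)

  # per-survey endorsement matrix, then day-level union
  ev_sets <- strsplit(s$events, ";", fixed = TRUE)
  E <- matrix(FALSE, nrow = nrow(s), ncol = 10, dimnames = list(NULL, cats))
  E[cbind(rep(seq_len(nrow(s)), lengths(ev_sets)),
          match(unlist(ev_sets), cats))] <- TRUE
  dayE <- rowsum(E + 0L, ki) > 0

  # prompt with the highest worry carries the day's most-stressful selection
  w_eff <- ifelse(is.na(s$worry), -1L, s$worry)
  pick <- order(ki, -w_eff, seq_len(nrow(s)))
  pick <- pick[!duplicated(ki[pick])]                  # one row per group
  pick <- pick[order(ki[pick])]

  first <- which(!duplicated(ki))
  mood_means <- rowsum(as.matrix(s[, mood_items()]), ki) / counts

  daily <- data.frame(participant_id = s$participant_id[first],
                      day = s$day[first], stringsAsFactors = FALSE)
  daily[mood_items()] <- as.data.frame(mood_means)
  daily$event_count <- as.integer(rowSums(dayE))
  daily$most_stressful_level <- pmax(w_eff[pick], 0L)
  daily[paste0("ev_", cats)] <- as.data.frame(dayE + 0L)
  ms_cat <- ifelse(w_eff[pick] >= 0, s$most_stressful[pick], "")
  for (cc in cats) daily[[paste0("ms_", cc)]] <- as.integer(ms_cat == cc)

  keep <- if (require_both) counts == ds$prompts_per_day else counts >= 1L
  daily <- daily[keep, , drop = FALSE]
  rownames(daily) <- NULL
  daily
}
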