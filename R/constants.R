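#' Canonical stressful-event categories
#'
#' The ten sources of minority-stress events recorded at each EMA prompt:
#' marriage, fertility, economy, housing, medical care, family discrimination,
#' working, learning, socializing, and other. Tokens are fixed; CSV files and
#' all per-category feature names use them verbatim.
#'
#' @return Character vector of length 10.
#' @export
event_categories <- function() {
  c("marriage", "fertility", "economy", "housing", "medical_care",
    "family", "working", "learning", "socializing", "other")
}

#' Mood item column names
#'
#' Six bipolar mood adjective pairs rated 0-6 at each prompt
#' (tired-awake, content-discontent, agitated-calm, energy, ill-well,
#' relaxed-tense).
#'
#' @return Character vector of length 6.
#' @export
mood_items <- function() {
  c("mood_tired_awake", "mood_content", "mood_agitated_calm",
    "mood_energy", "mood_ill_well", "mood_relaxed_tense")
}

#' Prompt slots
#' @return Character vector \code{c("morning", "evening")}.
#' @export
prompt_slots <- function() c("morning", "evening")

#' Follow-up horizons with a suicidal-ideation label
#' @return Character vector \code{c("1mo", "3mo", "8mo")}.
#' @export
outcome_horizons <- function() c("1mo", "3mo", "8mo")

#' Baseline predictor column names
#'
#' Seven enrollment predictors: baseline suicidal ideation, lifetime
#' non-suicidal self-injury frequency band, lifetime suicide attempt history,
#' psychiatric diagnosis history, psychiatric treatment history, family
#' history of suicide attempt, family history of psychiatric diagnosis.
#'
#' @return Character vector of length 7.
#' @export
baseline_predictors <- function() {
  c("baseline_si", "nssi_freq_band", "lifetime_attempt", "psych_dx_history",
    "psych_tx_history", "family_attempt_history", "family_dx_history")
}

# ordinal codebook for the lifetime NSSI frequency band
nssi_band_levels <- function() c("0", "1-10", "11-50", ">=51")

# dynamic day-level series summarised with mean/sd/slope/max_change/pac
dynamic_series_names <- function() {
  c(mood_items(), "event_count", "most_stressful_level")
}

# the EMA survey CSV header, bit-exact
ema_csv_header <- function() {
  c("participant_id", "day", "slot", mood_items(),
    "events", "most_stressful", "worry")
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}
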