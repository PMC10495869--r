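#' Simulation configuration for a synthetic EMA cohort
#'
#' Builds and validates the parameter set for [simulate_cohort()]. Defaults
#' describe a 25-day, twice-daily EMA study spanning three Lunar New Year
#' waves (days 1-8 before, 9-17 during, 18-25 after), with ~5.5% of surveys
#' missing completely at random, wave-2-elevated rates for the
#' marriage/fertility/family event categories, and logistic outcome models in
#' which the mood-instability effect decays with follow-up horizon while the
#' event-burden effect persists.
#'
#' @param n_participants Number of participants.
#' @param n_days EMA study length in days.
#' @param prompts_per_day Scheduled surveys per day (morning/evening).
#' @param wave_boundaries Two strictly increasing day indices; wave 1 is days
#'   `1..b1`, wave 2 `b1+1..b2`, wave 3 `b2+1..n_days`.
#' @param missing_rate Probability each scheduled survey is missing (MCAR,
#'   whole-survey level).
#' @param mood_ar_coef AR(1) coefficient of the shared latent mood process,
#'   in `[0, 1)`.
#' @param mood_noise_sd Median innovation SD of the latent mood process.
#' @param mood_vol_heterogeneity SD of the participant-level log-normal
#'   multiplier on `mood_noise_sd`. Affective instability is an individual
#'   difference: with the default 0.4, participants' volatilities span
#'   roughly a factor of 2 either way, giving the mood-instability latent
#'   real between-person variance (0 makes all participants equally
#'   volatile, leaving nothing for mood-dynamics features to predict).
#' @param event_base_rates Named length-10 vector of per-survey endorsement
#'   probabilities, one per category in [event_categories()].
#' @param wave2_multipliers Named length-10 vector of rate multipliers applied
#'   during wave 2 (default 3x for marriage, fertility, family).
#' @param event_weights Named length-10 vector weighting each category's
#'   contribution to the latent event-burden score that drives outcomes
#'   (default: marriage, fertility, economy, socializing only).
#' @param outcome_intercepts Length-4 logistic intercepts for the baseline,
#'   1-, 3- and 8-month suicidal-ideation models.
#' @param beta_mood Length-3 coefficients of standardized mood instability at
#'   the 1/3/8-month horizons (default decaying).
#' @param beta_event Length-3 coefficients of standardized event burden
#'   (default constant).
#' @param beta_baseline_si Coefficient of baseline suicidal ideation in the
#'   follow-up outcome models.
#' @param baseline_history_rates Named prevalences of the six non-SI baseline
#'   history predictors; `nssi_band_probs` gives the four band probabilities.
#' @param nssi_band_probs Probabilities of the four NSSI frequency bands.
#' @param seed Integer seed; all generation is deterministic given the config.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 103L,
                       n_days = 25L,
                       prompts_per_day = 2L,
                       wave_boundaries = c(8L, 17L),
                       missing_rate = 0.055,
                       mood_ar_coef = 0.6,
                       mood_noise_sd = 1,
                       mood_vol_heterogeneity = 0.4,
                       event_base_rates = default_event_rates(),
                       wave2_multipliers = default_wave2_multipliers(),
                       event_weights = default_event_weights(),
                       outcome_intercepts = c(-2.6, -2.2, -1.65, -1.5),
                       beta_mood = c(1.2, 0.6, 0.2),
                       beta_event = c(2, 2, 2),
                       beta_baseline_si = 0.8,
                       baseline_history_rates = c(
                         lifetime_attempt = 0.05, psych_dx_history = 0.35,
                         psych_tx_history = 0.30, family_attempt_history = 0.15,
                         family_dx_history = 0.15),
                       nssi_band_probs = c(0.61, 0.26, 0.09, 0.04),
                       seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants), n_days = as.integer(n_days),
    prompts_per_day = as.integer(prompts_per_day),
    wave_boundaries = as.integer(wave_boundaries),
    missing_rate = missing_rate, mood_ar_coef = mood_ar_coef,
    mood_noise_sd = mood_noise_sd,
    mood_vol_heterogeneity = mood_vol_heterogeneity,
    event_base_rates = complete_category_vector(event_base_rates, "event_base_rates"),
    wave2_multipliers = complete_category_vector(wave2_multipliers, "wave2_multipliers"),
    event_weights = complete_category_vector(event_weights, "event_weights"),
    outcome_intercepts = as.numeric(outcome_intercepts),
    beta_mood = as.numeric(beta_mood), beta_event = as.numeric(beta_event),
    beta_baseline_si = as.numeric(beta_baseline_si),
    baseline_history_rates = baseline_history_rates,
    nssi_band_probs = as.numeric(nssi_band_probs),
    seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @export
default_event_rates <- function() {
  c(marriage = 0.10, fertility = 0.08, economy = 0.12, housing = 0.05,
    medical_care = 0.04, family = 0.10, working = 0.12, learning = 0.10,
    socializing = 0.12, other = 0.06)
}

#' @rdname sim_config
#' @export
default_wave2_multipliers <- function() {
  m <- stats::setNames(rep(1, 10), event_categories())
  m[c("marriage", "fertility", "family")] <- 3
  m
}

#' @rdname sim_config
#' @export
default_event_weights <- function() {
  w <- stats::setNames(rep(0, 10), event_categories())
  w[c("marriage", "fertility", "economy", "socializing")] <- 1
  w
}

# accept a full named vector, or a partial one merged over zeros/ones
complete_category_vector <- function(x, field) {
  cats <- event_categories()
  if (is.null(names(x))) {
    if (length(x) != 10)
      stop_field(field, "must have length 10 or be named by category")
    return(stats::setNames(as.numeric(x), cats))
  }
  if (!all(names(x) %in% cats))
    stop_field(field, paste("unknown category:",
                            paste(setdiff(names(x), cats), collapse = ", ")))
  out <- stats::setNames(rep(NA_real_, 10), cats)
  out[names(x)] <- as.numeric(x)
  if (anyNA(out)) stop_field(field, "must name all 10 categories")
  out
}

validate_sim_config <- function(cfg) {
  if (cfg$n_participants < 1) stop_field("n_participants", "must be >= 1")
  if (cfg$n_days < 1) stop_field("n_days", "must be >= 1")
  if (cfg$prompts_per_day != 2L)
    stop_field("prompts_per_day", "only the morning/evening schedule (2) is supported")
  b <- cfg$wave_boundaries
  if (length(b) != 2 || b[1] >= b[2] || b[1] < 1 || b[2] >= cfg$n_days)
    stop_field("wave_boundaries",
               "must be two strictly increasing day indices inside 1..n_days-1")
  if (cfg$missing_rate < 0 || cfg$missing_rate > 1)
    stop_field("missing_rate", "must be a probability in [0,1]")
  if (cfg$mood_ar_coef < 0 || cfg$mood_ar_coef >= 1)
    stop_field("mood_ar_coef", "must be in [0,1)")
  if (cfg$mood_noise_sd <= 0) stop_field("mood_noise_sd", "must be positive")
  if (cfg$mood_vol_heterogeneity < 0)
    stop_field("mood_vol_heterogeneity", "must be nonnegative")
  if (any(cfg$event_base_rates < 0 | cfg$event_base_rates > 1))
    stop_field("event_base_rates", "must be probabilities in [0,1]")
  if (any(cfg$wave2_multipliers < 0))
    stop_field("wave2_multipliers", "must be nonnegative")
  if (length(cfg$outcome_intercepts) != 4)
    stop_field("outcome_intercepts", "must have length 4 (baseline, 1/3/8 months)")
  if (length(cfg$beta_mood) != 3) stop_field("beta_mood", "must have length 3")
  if (length(cfg$beta_event) != 3) stop_field("beta_event", "must have length 3")
  if (abs(sum(cfg$nssi_band_probs) - 1) > 1e-8 || any(cfg$nssi_band_probs < 0))
    stop_field("nssi_band_probs", "must be a probability vector summing to 1")
  if (any(cfg$baseline_history_rates < 0 | cfg$baseline_history_rates > 1))
    stop_field("baseline_history_rates", "must be probabilities in [0,1]")
  invisible(cfg)
}

#' Days belonging to each study wave
#'
#' @param n_days Study length.
#' @param wave_boundaries Two day indices; see [sim_config()].
#' @return List of three integer vectors (before / during / after).
#' @export
wave_days <- function(n_days = 25L, wave_boundaries = c(8L, 17L)) {
  b <- as.integer(wave_boundaries)
  n_days <- as.integer(n_days)
  list(wave1 = seq_len(min(b[1], n_days)),
       wave2 = if (b[1] < b[2]) seq.int(b[1] + 1L, min(b[2], n_days)) else integer(),
       wave3 = if (b[2] < n_days) seq.int(b[2] + 1L, n_days) else integer())
}

# fixed measurement model for the six ordinal mood items
mood_item_loadings <- function() c(1.0, 0.9, 0.8, 1.0, 0.7, 0.9)
mood_item_noise_sd <- function() 0.8

# fixed latent severity offsets used to pick the "most stressful" category
category_severity_offsets <- function() {
  stats::setNames(c(0.6, 0.5, 0.4, 0.1, 0.1, 0.6, 0.2, 0.2, 0.3, 0.0),
                  event_categories())
}

#' Generate a synthetic EMA cohort
#'
#' Draws, deterministically given `config$seed`:
#' \itemize{
#' \item a latent AR(1) mood path per participant over all prompts,
#'   discretized to the six ordinal items (0-6) through fixed loadings plus
#'   item noise;
#' \item per-survey, per-category Bernoulli stressful events whose rates are
#'   multiplied by `wave2_multipliers` on wave-2 days; the endorsed category
#'   with the highest latent severity draw becomes the "most stressful"
#'   selection, and a 0-6 worry rating is generated from that severity;
#' \item baseline history predictors, and suicidal-ideation labels at
#'   baseline and the 1/3/8-month horizons from logistic models in the
#'   standardized mood-instability latent (SD of successive latent mood
#'   changes), the standardized event-burden latent (weighted total event
#'   count) and baseline suicidal ideation.
#' }
#'
#' Survey-level missingness is applied afterwards with [apply_missingness()].
#'
#' @param config A [sim_config()].
#' @return List of class `ema_cohort` with elements `surveys` (long
#'   data.frame, one row per completed survey), `baselines` (one row per
#'   participant: 7 predictors), `outcomes` (one row per participant:
#'   `si_baseline`, `si_1mo`, `si_3mo`, `si_8mo`), `latents` (the generating
#'   scores, for calibration checks) and the `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_participants
  n_days <- config$n_days
  tt <- n_days * config$prompts_per_day       # prompts per participant
  cats <- event_categories()

  ids <- sprintf("P%04d", seq_len(n))

  # latent AR(1) mood, stationary start, one column per participant;
  # participants differ in volatility (log-normal innovation SD)
  phi <- config$mood_ar_coef
  sd_in <- config$mood_noise_sd *
    exp(stats::rnorm(n, 0, config$mood_vol_heterogeneity))
  lat <- matrix(0, nrow = tt, ncol = n)
  lat[1, ] <- stats::rnorm(n, 0, sd_in / sqrt(1 - phi^2))
  for (t in 2:tt)
    lat[t, ] <- phi * lat[t - 1, ] + stats::rnorm(n, 0, sd_in)

  # discretize to six ordinal items: clip(round(3 + loading*latent + noise), 0, 6)
  loadings <- mood_item_loadings()
  mood <- matrix(0L, nrow = tt * n, ncol = 6)
  latv <- as.vector(lat)                      # prompt-major within participant
  for (j in 1:6) {
    raw <- 3 + loadings[j] * latv + stats::rnorm(tt * n, 0, mood_item_noise_sd())
    mood[, j] <- pmin(6L, pmax(0L, as.integer(round(raw))))
  }

  day <- rep(rep(seq_len(n_days), each = config$prompts_per_day), times = n)
  slot <- rep(rep(prompt_slots(), times = n_days), times = n)
  pid <- rep(ids, each = tt)

  # per-survey per-category events, wave-2 days get multiplied rates
  wd <- wave_days(n_days, config$wave_boundaries)
  in_wave2 <- day %in% wd$wave2
  ev <- matrix(FALSE, nrow = tt * n, ncol = 10, dimnames = list(NULL, cats))
  for (k in seq_along(cats)) {
    rate <- ifelse(in_wave2,
                   pmin(1, config$event_base_rates[k] * config$wave2_multipliers[k]),
                   config$event_base_rates[k])
    ev[, k] <- stats::runif(tt * n) < rate
  }

  # most-stressful selection: endorsed category with the highest severity draw
  sev <- matrix(stats::rnorm(tt * n * 10), ncol = 10) +
    rep(category_severity_offsets(), each = tt * n)
  sev[!ev] <- -Inf
  any_ev <- rowSums(ev) > 0
  ms_idx <- max.col(sev, ties.method = "first")
  most_stressful <- ifelse(any_ev, cats[ms_idx], "")
  max_sev <- sev[cbind(seq_len(tt * n), ms_idx)]
  max_sev[!any_ev] <- 0            # unused; avoids -Inf in the worry draw
  worry_raw <- 2 + 0.8 * max_sev + stats::rnorm(tt * n, 0, 1)
  worry <- ifelse(any_ev, pmin(6L, pmax(0L, as.integer(round(worry_raw)))), NA_integer_)

  events_str <- apply(ev, 1L, function(r) paste(cats[r], collapse = ";"))

  surveys <- data.frame(participant_id = pid, day = day, slot = slot,
                        stringsAsFactors = FALSE)
  surveys[mood_items()] <- as.data.frame(mood)
  surveys$events <- events_str
  surveys$most_stressful <- most_stressful
  surveys$worry <- as.integer(worry)

  # latent scores driving outcomes (ground truth, pre-missingness)
  instab <- apply(lat, 2L, function(x) stats::sd(diff(x)))
  burden <- as.vector(tapply(
    as.vector(ev %*% config$event_weights), rep(seq_len(n), each = tt), sum))
  z_mood <- as.numeric(scale(instab))
  z_event <- as.numeric(scale(burden))
  if (n == 1) { z_mood <- 0; z_event <- 0 }    # scale() is NaN at n = 1

  a <- config$outcome_intercepts
  bm <- config$beta_mood; be <- config$beta_event
  si_baseline <- stats::rbinom(n, 1, stats::plogis(a[1] + bm[1] * z_mood + be[1] * z_event))
  p_h <- function(h) stats::plogis(a[h + 1] + bm[h] * z_mood + be[h] * z_event +
                                     config$beta_baseline_si * si_baseline)
  outcomes <- data.frame(participant_id = ids,
                         si_baseline = si_baseline,
                         si_1mo = stats::rbinom(n, 1, p_h(1)),
                         si_3mo = stats::rbinom(n, 1, p_h(2)),
                         si_8mo = stats::rbinom(n, 1, p_h(3)),
                         stringsAsFactors = FALSE)

  hr <- config$baseline_history_rates
  baselines <- data.frame(
    participant_id = ids,
    baseline_si = si_baseline,
    nssi_freq_band = sample(nssi_band_levels(), n, replace = TRUE,
                            prob = config$nssi_band_probs),
    lifetime_attempt = stats::rbinom(n, 1, hr[["lifetime_attempt"]]),
    psych_dx_history = stats::rbinom(n, 1, hr[["psych_dx_history"]]),
    psych_tx_history = stats::rbinom(n, 1, hr[["psych_tx_history"]]),
    family_attempt_history = stats::rbinom(n, 1, hr[["family_attempt_history"]]),
    family_dx_history = stats::rbinom(n, 1, hr[["family_dx_history"]]),
    stringsAsFactors = FALSE)

  surveys <- apply_missingness(surveys, config$missing_rate,
                               seed = config$seed + 1L)

  structure(list(surveys = surveys, baselines = baselines, outcomes = outcomes,
                 latents = data.frame(participant_id = ids,
                                      mood_instability = instab,
                                      event_burden = burden),
                 config = config),
            class = "ema_cohort")
}

#' Drop whole surveys at random
#'
#' Emulates survey-level (never item-level) missingness: each survey row is
#' independently removed with probability `missing_rate`.
#'
#' @param surveys Long survey data.frame.
#' @param missing_rate Probability in `[0,1]`.
#' @param seed Integer seed.
#' @return The retained survey rows.
#' @export
apply_missingness <- function(surveys, missing_rate, seed = 1L) {
  if (missing_rate < 0 || missing_rate > 1)
    stop_field("missing_rate", "must be a probability in [0,1]")
  if (missing_rate == 0) return(surveys)
  set.seed(as.integer(seed))
  keep <- stats::runif(nrow(surveys)) >= missing_rate
  surveys[keep, , drop = FALSE]
}

#' @export
print.ema_cohort <- function(x, ...) {
  cat(sprintf("ema_cohort: %d participants, %d days, %d completed surveys\n",
              nrow(x$baselines), x$config$n_days, nrow(x$surveys)))
  prev <- colMeans(x$outcomes[, -1])
  cat("SI prevalence:",
      paste(sprintf("%s %.1f%%", names(prev), 100 * prev), collapse = ", "), "\n")
  invisible(x)
}
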