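# Shared fixtures, built in code.

# small complete cohort used across modules
tiny_cohort <- function(n = 20, seed = 42, missing_rate = 0, ...) {
  simulate_cohort(sim_config(n_participants = n, missing_rate = missing_rate,
                             seed = seed, ...))
}

cohort_daily <- function(co) {
  ds <- ema_dataset(co$surveys, participants = co$baselines$participant_id,
                    n_days = co$config$n_days)
  day_aggregate(ds)
}

# hand-rolled survey rows for I/O tests
survey_row <- function(pid, day, slot, mood = rep(3L, 6), events = "",
                       most_stressful = "", worry = NA_integer_) {
  df <- data.frame(participant_id = pid, day = day, slot = slot,
                   stringsAsFactors = FALSE)
  df[mood_items()] <- as.list(as.integer(mood))
  df$events <- events
  df$most_stressful <- most_stressful
  df$worry <- worry
  df
}

write_survey_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  write_ema_csv(do.call(rbind, rows), path)
  path
}

# brute-force oracles, independent of the package implementation
oracle_summaries <- function(values, days) {
  fit <- stats::lm(values ~ days)
  list(mean = sum(values) / length(values),
       sd = sqrt(sum((values - mean(values))^2) / (length(values) - 1)),
       slope = unname(stats::coef(fit)[2]),
       max_change = max(abs(values[-1] - values[-length(values)])))
}

oracle_auc <- function(labels, scores) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(o == i)                       # rank of p[i]
    adj[i] <- min(vapply(r:m, function(j) m * p[o[j]] / j, numeric(1)), 1)
  }
  adj
}
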