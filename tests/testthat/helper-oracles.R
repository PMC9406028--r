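# Independent brute-force oracles and small fixture builders.
# Everything here recomputes quantities by direct enumeration / nested
# loops, deliberately not sharing code with the package internals.

# Minute-level Activity Index of one calendar day by direct nested loops
# over the per-epoch formulas: resultant norm per sample, population SD per
# 5 s epoch, sum of the 12 epoch SDs per minute. Missing minutes are NA.
brute_minute_ai <- function(stream) {
  tt <- as.numeric(stream$timestamp)
  day0 <- floor(min(tt) / 86400) * 86400
  ai <- rep(NA_real_, 1440)
  for (m in 0:1439) {
    sigmas <- c()
    for (k in 0:11) {
      lo <- day0 + m * 60 + k * 5
      sel <- tt >= lo & tt < lo + 5
      if (!any(sel)) next
      a <- numeric(0)
      for (j in which(sel)) {
        a <- c(a, sqrt(stream$ax[j]^2 + stream$ay[j]^2 + stream$az[j]^2))
      }
      mu <- sum(a) / length(a)
      sigmas <- c(sigmas, sqrt(sum((a - mu)^2) / length(a)))
    }
    if (length(sigmas) > 0) ai[m + 1] <- sum(sigmas)
  }
  ai
}

# Window label by scanning every following day individually.
oracle_label <- function(last_day, event_dates, obs_end, horizon = 30) {
  if (as.numeric(obs_end - last_day) < horizon) return("invalid")
  for (off in 1:horizon) {
    if ((last_day + off) %in% event_dates) return("positive")
  }
  "negative"
}

# TE/ME by scanning, for each event, every single prior day for a
# predicting window ending on it.
oracle_event_counts <- function(predictions, events, horizon = 30) {
  te <- 0L
  for (i in seq_len(nrow(events))) {
    e <- events$readmission_date[i]
    hit <- FALSE
    for (off in 1:horizon) {
      d <- e - off
      sel <- predictions$patient_id == events$patient_id[i] &
        predictions$last_day == d & predictions$predicted
      if (any(sel)) hit <- TRUE
    }
    if (hit) te <- te + 1L
  }
  list(te = te, me = nrow(events) - te)
}

# TP/FP by scanning each predicted window's 30 following days.
oracle_prediction_counts <- function(predictions, events, horizon = 30) {
  tp <- 0L; fp <- 0L
  for (i in which(predictions$predicted)) {
    found <- FALSE
    for (off in 1:horizon) {
      d <- predictions$last_day[i] + off
      sel <- events$patient_id == predictions$patient_id[i] &
        events$readmission_date == d
      if (any(sel)) found <- TRUE
    }
    if (found) tp <- tp + 1L else fp <- fp + 1L
  }
  list(tp = tp, fp = fp)
}

# Minimal daily-features table: wear-valid days with prescribed AI sums.
make_daily <- function(patient_id, dates, ai_sum = 100, wear_valid = TRUE,
                       ri = 0.5) {
  n <- length(dates)
  ai_sum <- rep_len(ai_sum, n)
  wear_valid <- rep_len(wear_valid, n)
  data.frame(
    patient_id = patient_id, date = dates, wear_valid = wear_valid,
    wear_seconds = ifelse(wear_valid, 86400, 36000),
    ai_sum = ai_sum, ai_mean = ai_sum / 1440,
    ai_median = ai_sum / 1440, ai_cov = 0.5,
    ri = rep_len(ri, n), qoa = ai_sum * (1 + rep_len(ri, n))
  )
}

# Deterministic raw one-day (or partial-day) stream: within each minute the
# resultant magnitude alternates 1 - amp / 1 + amp (alternation along the
# gravity axis), so every epoch's population SD equals amp exactly and the
# minute AI equals 12 * amp. `samples_per_epoch` must be even; amp < 1.
deterministic_stream <- function(day_start, minutes, amp_per_minute,
                                 samples_per_epoch = 4) {
  k <- samples_per_epoch
  per_min <- 12 * k
  within <- rep(0:11 * 5, each = k) + rep(seq(0, 4.5, length.out = k), 12)
  tt <- as.numeric(day_start) + rep(minutes * 60, each = per_min) +
    rep(within, length(minutes))
  sgn <- rep(rep_len(c(-1, 1), per_min), length(minutes))
  data.frame(
    timestamp = as.POSIXct(tt, origin = "1970-01-01", tz = "UTC"),
    ax = 0, ay = 0,
    az = 1 + sgn * rep(amp_per_minute, each = per_min)
  )
}

# Expand one window into its set of patient-day keys (for leakage checks).
window_days <- function(windows, window_length = 7) {
  out <- character(0)
  for (i in seq_len(nrow(windows))) {
    d <- windows$first_day[i] + 0:(window_length - 1)
    out <- c(out, paste(windows$patient_id[i], d))
  }
  out
}

small_cohort_config <- function(...) {
  cohort_config(n_patients = 3, days_per_patient = 60, ...)
}
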