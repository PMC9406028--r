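#' Resultant acceleration
#'
#' Euclidean norm of the three orthogonal acceleration components at one
#' sample instant, in g-units. Vectorized over samples.
#'
#' @param ax,ay,az Accelerations (g) along the x, y and z axes.
#' @return Nonnegative resultant acceleration(s) (g).
#' @export
#' @examples
#' resultant_acceleration(3, 4, 0)  # 5
resultant_acceleration <- function(ax, ay, az) {
  if (!all(is.finite(ax), is.finite(ay), is.finite(az))) {
    stop("non-finite acceleration sample", call. = FALSE)
  }
  sqrt(ax^2 + ay^2 + az^2)
}

#' Per-epoch mean and standard deviation of resultant acceleration
#'
#' Summarizes one 5-second epoch of resultant-acceleration values. The SD is
#' the population SD (divisor N, not N-1); subtracting the epoch mean removes
#' the constant gravity component, so sigma quantifies actual physical
#' activity within the epoch.
#'
#' @param samples Resultant accelerations (g) belonging to one epoch; at
#'   most 100 values at full wear (20 Hz x 5 s). An empty epoch is a missing
#'   epoch, returned as `NA`, never as zero.
#' @return A list with `mu` (mean, g), `sigma` (population SD, g) and
#'   `n_samples`.
#' @export
#' @examples
#' epoch_stats(c(1, 3))  # mu 2, sigma 1
epoch_stats <- function(samples) {
  n <- length(samples)
  if (n == 0) {
    return(list(mu = NA_real_, sigma = NA_real_, n_samples = 0L))
  }
  mu <- mean(samples)
  list(mu = mu, sigma = sqrt(mean((samples - mu)^2)), n_samples = n)
}

#' Minute-level Activity Index
#'
#' The Activity Index (AI) of one minute is the sum of the 12 per-epoch
#' resultant-acceleration SDs covering that minute (12 x 5 s = 60 s).
#' Missing epochs are excluded from the sum; a minute with all 12 epochs
#' missing is itself missing.
#'
#' @param epoch_sigmas Numeric vector of up to 12 per-epoch SDs (g); `NA`
#'   marks a missing epoch.
#' @return The AI (g), with attribute `coverage` giving the fraction of the
#'   12 epoch slots present; `NA` when no epoch is present.
#' @export
minute_activity_index <- function(epoch_sigmas) {
  if (length(epoch_sigmas) > 12) {
    stop("a minute has at most 12 five-second epochs", call. = FALSE)
  }
  present <- sum(!is.na(epoch_sigmas))
  ai <- if (present == 0) NA_real_ else sum(epoch_sigmas, na.rm = TRUE)
  structure(ai, coverage = present / 12)
}

#' Hourly physical-activity sum
#'
#' Sum of the 60 minute-level AI values of one clock hour, over non-missing
#' minutes. An hour with no recorded minutes is missing.
#'
#' @param minute_ai Numeric vector of 60 minute AI values (`NA` = missing).
#' @return The hourly PA sum (g), or `NA` when all minutes are missing.
#' @export
hourly_pa_sum <- function(minute_ai) {
  stopifnot(length(minute_ai) == 60)
  if (all(is.na(minute_ai))) return(NA_real_)
  sum(minute_ai, na.rm = TRUE)
}

#' Regularity Index of a day pair
#'
#' Pearson correlation between the 24 hourly-PA sums of day `d - 1` and day
#' `d`; quantifies day-to-day regularity of the activity routine. Undefined
#' (returned as `NA`) when either day's pattern has zero variance or when no
#' previous day exists.
#'
#' @param hourly_prev,hourly_curr 24-vectors of hourly PA sums for days
#'   `d - 1` and `d`.
#' @return Correlation in `[-1, 1]`, or `NA` when undefined.
#' @export
regularity_index <- function(hourly_prev, hourly_curr) {
  stopifnot(length(hourly_prev) == 24, length(hourly_curr) == 24)
  if (anyNA(hourly_prev) || anyNA(hourly_curr)) return(NA_real_)
  if (stats::sd(hourly_prev) == 0 || stats::sd(hourly_curr) == 0) {
    return(NA_real_)
  }
  stats::cor(hourly_prev, hourly_curr)
}

#' Daily Quality of Activity
#'
#' QoA blends activity volume with routine regularity:
#' `(sum of the day's minute AI) * (1 + RI)`. It is nonnegative because RI is
#' at least -1. When RI is undefined (first observed day, invalid neighbour
#' day, or a zero-variance pattern) a regularity-neutral RI of 0 is
#' substituted so QoA degrades gracefully to the plain daily AI sum.
#'
#' @param minute_ai Numeric vector of the day's minute AI values (up to
#'   1440; `NA` = missing minute).
#' @param ri The day's Regularity Index, possibly `NA`.
#' @return QoA (g), nonnegative.
#' @export
daily_qoa <- function(minute_ai, ri) {
  if (length(minute_ai) > 1440) {
    stop("a day has at most 1440 minutes", call. = FALSE)
  }
  if (is.na(ri)) ri <- 0
  stopifnot(ri >= -1, ri <= 1)
  sum(minute_ai, na.rm = TRUE) * (1 + ri)
}

#' Wear validity of one calendar day
#'
#' A day enters the analysis only if at least `min_wear_hours` (default 16)
#' of physical-activity data were recorded over the 24-hour period. Coverage
#' is cumulative over the day's 5-second epochs; optionally a maximum single
#' internal gap can additionally be required.
#'
#' @param day_stream Data.frame with a POSIXct `timestamp` column, all
#'   samples belonging to one calendar day (UTC).
#' @param min_wear_hours Minimum recorded hours for validity.
#' @param max_gap_hours Maximum allowed single internal gap (hours) between
#'   recorded epochs; `Inf` (default) for the purely cumulative rule.
#' @return A list with `wear_valid` (logical) and `wear_seconds` (seconds of
#'   recorded data, at 5-second resolution).
#' @export
wear_validity <- function(day_stream, min_wear_hours = 16,
                          max_gap_hours = Inf) {
  tt <- as.numeric(day_stream$timestamp)
  if (length(tt) == 0) return(list(wear_valid = FALSE, wear_seconds = 0))
  day0 <- floor(tt / 86400)
  if (length(unique(day0)) > 1) {
    stop("samples span more than one calendar day", call. = FALSE)
  }
  ep <- sort(unique(floor((tt - day0[1] * 86400) / 5)))
  wear_seconds <- 5 * length(ep)
  valid <- wear_seconds >= min_wear_hours * 3600
  if (is.finite(max_gap_hours) && length(ep) > 1) {
    max_gap <- max(diff(ep) - 1) * 5
    valid <- valid && max_gap <= max_gap_hours * 3600
  }
  list(wear_valid = valid, wear_seconds = wear_seconds)
}

#' @keywords internal
#' Assemble the per-day feature table from a days x 1440 minute-AI matrix
#' (NA = missing minute) and per-day wear seconds. RI chains consecutive
#' wear-valid days only; hours with no recorded minutes contribute zero to
#' the daily 24-hour pattern.
summarize_days <- function(patient_id, dates, ai, wear_seconds,
                           min_wear_hours = 16, wear_valid = NULL) {
  D <- length(dates)
  stopifnot(nrow(ai) == D, ncol(ai) == 1440)
  if (is.null(wear_valid)) {
    wear_valid <- wear_seconds >= min_wear_hours * 3600
  }
  ai0 <- ai
  ai0[is.na(ai0)] <- 0
  hour_ind <- outer(rep(0:23, each = 60), 0:23, "==") * 1  # 1440 x 24
  hourly <- ai0 %*% hour_ind
  ri <- rep(NA_real_, D)
  for (d in seq_len(D)[-1]) {
    if (wear_valid[d] && wear_valid[d - 1] &&
        stats::sd(hourly[d, ]) > 0 && stats::sd(hourly[d - 1, ]) > 0) {
      ri[d] <- stats::cor(hourly[d - 1, ], hourly[d, ])
    }
  }
  ai_sum <- rowSums(ai, na.rm = TRUE)
  ai_mean <- numeric(D); ai_median <- numeric(D); ai_cov <- numeric(D)
  for (d in seq_len(D)) {
    v <- ai[d, ]
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      ai_mean[d] <- 0; ai_median[d] <- 0; ai_cov[d] <- 0
    } else {
      ai_mean[d] <- mean(v)
      ai_median[d] <- stats::median(v)
      ai_cov[d] <- if (ai_mean[d] == 0) 0 else stats::sd(v) / ai_mean[d]
    }
  }
  qoa <- ai_sum * (1 + ifelse(is.na(ri), 0, ri))
  out <- data.frame(
    patient_id = patient_id,
    date = dates,
    wear_valid = wear_valid,
    wear_seconds = as.numeric(wear_seconds),
    ai_sum = ai_sum,
    ai_mean = ai_mean,
    ai_median = ai_median,
    ai_cov = ai_cov,
    ri = ri,
    qoa = qoa
  )
  rownames(out) <- NULL
  attr(out, "minute_ai") <- ai
  attr(out, "hourly_pa") <- hourly
  out
}

#' Extract daily activity features from a raw accelerometer stream
#'
#' Runs the full per-day feature chain on a tri-axial stream: resultant
#' acceleration per sample, population mean/SD per 5-second epoch, minute
#' Activity Index (sum of 12 epoch SDs), hourly PA sums, day-pair Regularity
#' Index (chained over consecutive wear-valid days only), daily Quality of
#' Activity, and the 16-hour wear-validity rule. Epochs, minutes and hours
#' are aligned to wall-clock boundaries of the 00:00-anchored UTC day.
#'
#' @param stream Data.frame `timestamp, ax, ay, az` (POSIXct UTC; g-units),
#'   strictly time-ordered; gaps are absent rows.
#' @param patient_id Identifier recorded in the output.
#' @param date_range Optional Date vector `c(first, last)`; days in the range
#'   without data still get a (non-wear-valid) row.
#' @param min_wear_hours,max_gap_hours Wear-validity rule, see
#'   [wear_validity()].
#' @return A data.frame with one row per calendar day and columns
#'   `patient_id, date, wear_valid, wear_seconds, ai_sum, ai_mean, ai_median,
#'   ai_cov, ri, qoa`. `ai_*` summarize the day's non-missing minute AI
#'   values (CoV = SD/mean); the full days x 1440 minute-AI matrix and the
#'   days x 24 hourly-PA matrix are attached as attributes `minute_ai` and
#'   `hourly_pa`.
#' @export
extract_daily_features <- function(stream, patient_id = "P01",
                                   date_range = NULL, min_wear_hours = 16,
                                   max_gap_hours = Inf) {
  tt <- as.numeric(stream$timestamp)
  if (is.unsorted(tt)) {
    stop("stream timestamps must be non-decreasing", call. = FALSE)
  }
  a <- resultant_acceleration(stream$ax, stream$ay, stream$az)
  dayn <- floor(tt / 86400)
  epoch <- as.integer(floor((tt - dayn * 86400) / 5))  # 0..17279
  DT <- data.table::data.table(day = dayn, epoch = epoch, a = a)
  es <- DT[, list(n = .N, mu = mean(a),
                  sigma = sqrt(mean((a - mean(a))^2))),
           by = c("day", "epoch")]
  es[, "minute" := es$epoch %/% 12L]
  mi <- es[, list(ai = sum(sigma), n_ep = .N), by = c("day", "minute")]
  ws <- es[, list(wear_seconds = 5 * .N,
                  max_gap = if (.N > 1) max(diff(sort(epoch)) - 1L) * 5 else 0),
           by = "day"]

  if (is.null(date_range)) {
    if (nrow(ws) == 0) stop("empty stream and no date_range", call. = FALSE)
    days <- seq(min(ws$day), max(ws$day))
  } else {
    dr <- as.integer(as.Date(date_range))
    days <- seq(dr[1], dr[length(dr)])
  }
  D <- length(days)
  ai <- matrix(NA_real_, nrow = D, ncol = 1440)
  di <- match(mi$day, days)
  keep <- !is.na(di)
  ai[cbind(di[keep], mi$minute[keep] + 1L)] <- mi$ai[keep]
  wear_seconds <- rep(0, D)
  wi <- match(ws$day, days)
  keep <- !is.na(wi)
  wear_seconds[wi[keep]] <- ws$wear_seconds[keep]
  valid <- wear_seconds >= min_wear_hours * 3600
  if (is.finite(max_gap_hours)) {
    gap_ok <- rep(TRUE, D)
    gap_ok[wi[keep]] <- ws$max_gap[keep] <= max_gap_hours * 3600
    valid <- valid & gap_ok
  }
  summarize_days(patient_id, as.Date(days, origin = "1970-01-01"),
                 ai, wear_seconds, min_wear_hours, wear_valid = valid)
}
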