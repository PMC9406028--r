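#' Configuration for a synthetic wearable cohort
#'
#' Defines the statistical structure of a simulated COPD cohort wearing a
#' wrist accelerometer: circadian day/night activity, Poisson activity bouts,
#' non-wear gaps, scheduled hospital readmissions, and a progressive decline
#' in activity intensity over a configurable window before each readmission.
#'
#' The defaults emulate the scale of a 16-patient cohort observed over about
#' 3900 patient-days, with roughly 21 readmission events in total.
#'
#' @param n_patients Number of patients to simulate.
#' @param days_per_patient Calendar days of observation per patient.
#' @param sampling_rate Accelerometer sampling rate in samples/second. Must
#'   yield an integer number of samples per 5-second epoch.
#' @param night_activity_level SD (g) of resting accelerometer jitter around
#'   the 1 g gravity baseline (night, and daytime outside bouts).
#' @param day_activity_level SD (g) of acceleration during active daytime
#'   bouts.
#' @param bout_rate Expected active bouts per daytime hour (Poisson).
#' @param bout_duration Duration of one bout in minutes.
#' @param readmission_hazard Per-day probability of scheduling a readmission
#'   (with a 30-day refractory period after each event).
#' @param decline_days Days over which bout amplitude ramps down before a
#'   scheduled readmission.
#' @param decline_floor Multiplicative bout-amplitude attenuation reached on
#'   the event day itself, in `[0, 1]`.
#' @param nonwear_rate Expected non-wear gaps per day (Poisson).
#' @param nonwear_duration Duration of one non-wear gap in hours.
#' @param observation_start Calendar date of the first observation day.
#' @param seed Integer RNG seed; identical configurations produce
#'   byte-identical cohorts.
#' @return An object of class `cohort_config` (a validated list).
#' @export
#' @examples
#' cfg <- cohort_config(n_patients = 2, days_per_patient = 10)
#' cfg$n_patients
cohort_config <- function(n_patients = 16,
                          days_per_patient = 243,
                          sampling_rate = 20,
                          night_activity_level = 0.01,
                          day_activity_level = 0.08,
                          bout_rate = 2,
                          bout_duration = 10,
                          readmission_hazard = 0.0055,
                          decline_days = 10,
                          decline_floor = 0.5,
                          nonwear_rate = 0.3,
                          nonwear_duration = 6,
                          observation_start = as.Date("2016-04-01"),
                          seed = 1L) {
  stopifnot(
    n_patients >= 0, days_per_patient >= 0,
    sampling_rate > 0,
    night_activity_level >= 0, day_activity_level >= 0,
    bout_rate >= 0, bout_duration >= 1,
    readmission_hazard >= 0, readmission_hazard <= 1,
    decline_days >= 0,
    nonwear_rate >= 0, nonwear_duration > 0
  )
  if (decline_floor < 0 || decline_floor > 1) {
    stop("`decline_floor` must lie in [0, 1]", call. = FALSE)
  }
  n_epoch <- sampling_rate * 5
  if (abs(n_epoch - round(n_epoch)) > 1e-9) {
    stop("`sampling_rate` must give an integer number of samples per ",
         "5-second epoch (sampling_rate * 5)", call. = FALSE)
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      days_per_patient = as.integer(days_per_patient),
      sampling_rate = sampling_rate,
      night_activity_level = night_activity_level,
      day_activity_level = day_activity_level,
      bout_rate = bout_rate,
      bout_duration = as.integer(bout_duration),
      readmission_hazard = readmission_hazard,
      decline_days = as.integer(decline_days),
      decline_floor = decline_floor,
      nonwear_rate = nonwear_rate,
      nonwear_duration = nonwear_duration,
      observation_start = as.Date(observation_start),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# Minimum separation (days) between scheduled readmissions: a readmission
# implies a hospital stay and restarts the 30-day readmission clock.
EVENT_REFRACTORY_DAYS <- 30L

# Daytime minutes eligible for activity bouts: 06:00-24:00 (0-based minute
# indices 360..1439); 00:00-06:00 is the low-activity night state.
DAY_MINUTES <- 360:1439

#' @keywords internal
#' Draw the per-patient activity schedule shared by both generator outputs:
#' per-minute activity SD (g), per-minute wear mask, and event day indices.
patient_schedule <- function(config) {
  D <- config$days_per_patient
  # readmission days: daily hazard with refractory period
  u <- stats::runif(D)
  event_days <- integer(0)
  last <- -Inf
  for (d in seq_len(D)) {
    if (d - last >= EVENT_REFRACTORY_DAYS && u[d] < config$readmission_hazard) {
      event_days <- c(event_days, d)
      last <- d
    }
  }
  # multiplicative bout-amplitude factor: ramps 1 -> decline_floor linearly
  # over decline_days before each event; overlapping ramps take the minimum
  decl <- rep(1, D)
  for (e in event_days) {
    if (config$decline_days > 0) {
      ds <- max(1L, e - config$decline_days):e
      frac <- (ds - (e - config$decline_days)) / config$decline_days
      decl[ds] <- pmin(decl[ds], 1 + (config$decline_floor - 1) * frac)
    } else {
      decl[e] <- min(decl[e], config$decline_floor)
    }
  }
  # per-minute activity SD: resting jitter everywhere, bout level during
  # Poisson-placed daytime bouts (attenuated in the decline window)
  sdm <- matrix(config$night_activity_level, nrow = D, ncol = 1440)
  for (d in seq_len(D)) {
    n_bouts <- stats::rpois(1, config$bout_rate * length(DAY_MINUTES) / 60)
    if (n_bouts > 0) {
      starts <- sample(DAY_MINUTES, n_bouts, replace = TRUE)
      lvl <- config$day_activity_level * decl[d]
      for (s in starts) {
        idx <- (s + 1L):min(1440L, s + config$bout_duration)
        sdm[d, idx] <- pmax(sdm[d, idx], lvl)
      }
    }
  }
  # non-wear gaps: whole-minute spans removed from the record
  wear <- matrix(TRUE, nrow = D, ncol = 1440)
  for (d in seq_len(D)) {
    n_gaps <- stats::rpois(1, config$nonwear_rate)
    if (n_gaps > 0) {
      len <- as.integer(round(config$nonwear_duration * 60))
      starts <- sample.int(1440L, n_gaps, replace = TRUE) - 1L
      for (s in starts) {
        idx <- (s + 1L):min(1440L, s + len)
        wear[d, idx] <- FALSE
      }
    }
  }
  list(sd = sdm, wear = wear, event_days = event_days)
}

#' @keywords internal
#' Expand a schedule into a raw tri-axial sample stream. Gravity is a unit
#' vector along z; per-axis noise has the minute's activity SD. Non-wear
#' minutes are absent rows, not zeros.
schedule_to_stream <- function(config, schedule) {
  D <- config$days_per_patient
  k <- as.integer(round(config$sampling_rate * 60))
  wear_idx <- which(t(schedule$wear))  # row-major: day-major minute order
  if (length(wear_idx) == 0) {
    return(data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                      ax = numeric(), ay = numeric(), az = numeric()))
  }
  minute0 <- (wear_idx - 1L) %% 1440L        # minute of day, 0-based
  day0 <- (wear_idx - 1L) %/% 1440L          # day index, 0-based
  sd_min <- t(schedule$sd)[wear_idx]
  base <- as.numeric(as.POSIXct(config$observation_start, tz = "UTC")) +
    day0 * 86400 + minute0 * 60
  n <- length(wear_idx) * k
  tt <- rep(base, each = k) + rep(seq(0, by = 1 / config$sampling_rate,
                                      length.out = k), times = length(base))
  sdv <- rep(sd_min, each = k)
  data.frame(
    timestamp = as.POSIXct(tt, origin = "1970-01-01", tz = "UTC"),
    ax = stats::rnorm(n, 0, sdv),
    ay = stats::rnorm(n, 0, sdv),
    az = 1 + stats::rnorm(n, 0, sdv)
  )
}

#' @keywords internal
#' Minute-level Activity Index drawn directly from the sampling distribution
#' implied by the raw model: within one 5 s epoch of N samples with activity
#' SD s, the population SD of the resultant acceleration is distributed as
#' s * sqrt(chisq(N-1) / N) (the gravity baseline cancels), and a minute's AI
#' is the sum of 12 such epochs. A normal approximation to that 12-fold sum
#' is used, truncated at zero.
schedule_to_daily <- function(config, schedule, patient_id) {
  D <- config$days_per_patient
  N <- as.integer(round(config$sampling_rate * 5))
  # exact mean/variance of sqrt(chisq(N-1)/N)
  e1 <- sqrt(2 / N) * exp(lgamma(N / 2) - lgamma((N - 1) / 2))
  v1 <- (N - 1) / N - e1^2
  ai <- matrix(NA_real_, nrow = D, ncol = 1440)
  widx <- which(schedule$wear)
  if (length(widx) > 0) {
    draw <- stats::rnorm(length(widx), mean = 12 * e1, sd = sqrt(12 * v1))
    ai[widx] <- pmax(0, schedule$sd[widx] * draw)
  }
  dates <- config$observation_start + 0:(D - 1)
  wear_seconds <- 60 * rowSums(schedule$wear)
  summarize_days(patient_id, dates, ai, wear_seconds)
}

#' Simulate one patient's accelerometer record and event log
#'
#' @param config A [cohort_config()].
#' @param patient_id Identifier string for the patient.
#' @param seed Integer substream seed for this patient.
#' @param output `"raw"` for a per-sample tri-axial stream (feasible for
#'   short records), `"daily"` for day-level features drawn from the same
#'   activity schedule (feasible at cohort scale).
#' @return A list with elements `patient_id`, `events` (Date vector of
#'   readmission dates), `observation_start`, `observation_end`, and either
#'   `stream` (data.frame `timestamp, ax, ay, az`) or `daily` (a
#'   daily-features data.frame, see [extract_daily_features()]).
#' @export
generate_patient <- function(config, patient_id, seed,
                             output = c("raw", "daily")) {
  output <- match.arg(output)
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(seed %% .Machine$integer.max))
  sched <- patient_schedule(config)
  out <- list(
    patient_id = patient_id,
    events = config$observation_start + (sched$event_days - 1L),
    observation_start = config$observation_start,
    observation_end = config$observation_start + config$days_per_patient - 1L
  )
  if (output == "raw") {
    out$stream <- schedule_to_stream(config, sched)
  } else {
    out$daily <- schedule_to_daily(config, sched, patient_id)
  }
  out
}

#' Simulate a synthetic wearable cohort
#'
#' Deterministic fan-out of [generate_patient()] with per-patient derived
#' seeds: the same configuration always yields the same cohort.
#'
#' @inheritParams generate_patient
#' @return An object of class `pa_cohort`: a list with `config`, `patients`
#'   (per-patient output of [generate_patient()]), `events` (data.frame
#'   `patient_id, readmission_date`), `observation` (data.frame
#'   `patient_id, start, end`), and — when `output = "daily"` — `daily`, the
#'   row-bound daily-features table for the whole cohort.
#' @export
#' @examples
#' co <- simulate_cohort(cohort_config(n_patients = 2, days_per_patient = 40),
#'                       output = "daily")
#' nrow(co$daily)  # 2 * 40 patient-days
simulate_cohort <- function(config, output = c("daily", "raw")) {
  output <- match.arg(output)
  stopifnot(inherits(config, "cohort_config"))
  ids <- sprintf("P%02d", seq_len(config$n_patients))
  patients <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    sub_seed <- (config$seed + 7919L * i) %% .Machine$integer.max
    patients[[i]] <- generate_patient(config, ids[i], sub_seed, output)
  }
  events <- do.call(rbind, lapply(patients, function(p) {
    if (length(p$events) == 0) return(NULL)
    data.frame(patient_id = p$patient_id, readmission_date = p$events)
  }))
  if (is.null(events)) {
    events <- data.frame(patient_id = character(),
                         readmission_date = as.Date(character()))
  }
  observation <- do.call(rbind, lapply(patients, function(p) {
    data.frame(patient_id = p$patient_id, start = p$observation_start,
               end = p$observation_end)
  }))
  if (is.null(observation)) {
    observation <- data.frame(patient_id = character(),
                              start = as.Date(character()),
                              end = as.Date(character()))
  }
  out <- list(config = config, patients = patients,
              events = events, observation = observation)
  if (output == "daily") {
    out$daily <- do.call(rbind, lapply(patients, `[[`, "daily"))
  }
  class(out) <- "pa_cohort"
  out
}

#' Write a simulated cohort to disk
#'
#' Writes one accelerometer CSV per patient (raw cohorts; header
#' `timestamp,ax,ay,az`, ISO-8601 timestamps, gaps as absent rows) or a single
#' daily-features CSV (daily cohorts), the event log CSV (header
#' `patient_id,readmission_date`) and a manifest JSON with the observation
#' windows and the full generating configuration, for provenance.
#'
#' @param cohort A `pa_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pa_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (p in cohort$patients) {
    if (!is.null(p$stream)) {
      f <- file.path(dir, paste0("accel_", p$patient_id, ".csv"))
      s <- p$stream
      s$timestamp <- format(s$timestamp, "%Y-%m-%dT%H:%M:%OS2Z", tz = "UTC")
      data.table::fwrite(s, f)
      files <- c(files, f)
    }
  }
  if (!is.null(cohort$daily)) {
    f <- file.path(dir, "daily_features.csv")
    data.table::fwrite(cohort$daily, f)
    files <- c(files, f)
  }
  fe <- file.path(dir, "events.csv")
  data.table::fwrite(cohort$events, fe)
  fm <- file.path(dir, "manifest.json")
  cfg <- cohort$config
  cfg$observation_start <- as.character(cfg$observation_start)
  manifest <- list(
    config = unclass(cfg),
    observation = data.frame(
      patient_id = cohort$observation$patient_id,
      start = as.character(cohort$observation$start),
      end = as.character(cohort$observation$end)
    )
  )
  jsonlite::write_json(manifest, fm, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(files, fe, fm))
}

#' Read an accelerometer stream CSV
#'
#' @param path CSV with header `timestamp,ax,ay,az` and ISO-8601 timestamps.
#' @return A data.frame with a POSIXct `timestamp` column (UTC) and numeric
#'   `ax`, `ay`, `az` in g-units.
#' @export
read_accel_csv <- function(path) {
  d <- data.table::fread(path, colClasses = list(character = "timestamp"))
  d <- as.data.frame(d)
  d$timestamp <- as.POSIXct(sub("Z$", "", d$timestamp),
                            format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  if (any(is.na(d$timestamp))) stop("unparseable timestamps in ", path)
  d
}

#' Read a readmission event log CSV
#'
#' @param path CSV with header `patient_id,readmission_date`.
#' @return A data.frame with `patient_id` and Date `readmission_date`,
#'   sorted and strictly increasing within patient.
#' @export
read_event_log <- function(path) {
  d <- as.data.frame(data.table::fread(path))
  d$readmission_date <- as.Date(d$readmission_date)
  d <- d[order(d$patient_id, d$readmission_date), , drop = FALSE]
  for (pid in unique(d$patient_id)) {
    dd <- d$readmission_date[d$patient_id == pid]
    if (anyDuplicated(dd)) stop("duplicate readmission dates for ", pid)
  }
  rownames(d) <- NULL
  d
}
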