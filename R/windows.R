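#' Build overlapping 7-day physical-activity windows
#'
#' One window ("dataset") is 7 consecutive wear-valid calendar days of daily
#' features; windows slide by one day within each maximal run of consecutive
#' wear-valid days, so they overlap. The readmission predicted from a window
#' refers to the day after its last day. Windows whose 7-day span contains a
#' readmission date are dropped: days around a hospitalization must not feed
#' the at-home activity model.
#'
#' @param daily Daily-features data.frame (one or more patients), as
#'   produced by [extract_daily_features()] or [simulate_cohort()].
#' @param events Optional event log data.frame
#'   (`patient_id, readmission_date`); used to drop hospitalization-spanning
#'   windows.
#' @param window_length Days per window (default 7).
#' @return Data.frame `patient_id, first_day, last_day, prediction_date`
#'   (`prediction_date = last_day + 1`), sorted by patient and time.
#' @export
build_windows <- function(daily, events = NULL, window_length = 7) {
  stopifnot(window_length >= 2)
  out <- list()
  for (pid in unique(daily$patient_id)) {
    dd <- daily[daily$patient_id == pid & daily$wear_valid, , drop = FALSE]
    if (nrow(dd) < window_length) next
    dates <- sort(dd$date)
    # maximal runs of consecutive calendar days
    brk <- c(0, which(diff(dates) != 1), length(dates))
    ev <- if (is.null(events)) as.Date(character()) else
      events$readmission_date[events$patient_id == pid]
    for (r in seq_len(length(brk) - 1)) {
      run <- dates[(brk[r] + 1):brk[r + 1]]
      if (length(run) < window_length) next
      last_days <- run[window_length:length(run)]
      first_days <- last_days - (window_length - 1)
      keep <- vapply(seq_along(last_days), function(i) {
        !any(ev >= first_days[i] & ev <= last_days[i])
      }, logical(1))
      if (!any(keep)) next
      out[[length(out) + 1]] <- data.frame(
        patient_id = pid,
        first_day = first_days[keep],
        last_day = last_days[keep],
        prediction_date = last_days[keep] + 1
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(patient_id = character(),
                      first_day = as.Date(character()),
                      last_day = as.Date(character()),
                      prediction_date = as.Date(character())))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$patient_id, res$last_day), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Label windows against the readmission log
#'
#' A window is *valid* only when actual hospital information is available for
#' the 30 days after its last day (`last_day + horizon <= observation_end`):
#' otherwise its prediction could not be adjudicated. A valid window is
#' *positive* when a readmission occurred within the subsequent `horizon`
#' days — the interval `(last_day, last_day + horizon]`, so an event on the
#' last recorded day does not count as a future readmission while one exactly
#' `horizon` days later does — and *negative* otherwise.
#'
#' @param windows Window table from [build_windows()].
#' @param events Event log (`patient_id, readmission_date`).
#' @param observation Data.frame `patient_id, start, end` giving each
#'   patient's clinical follow-up period. Every windowed patient must appear.
#' @param horizon Lookahead horizon in days (default 30).
#' @return `windows` with columns `validity` (`"valid"`/`"invalid"`),
#'   `label` (`"positive"`/`"negative"`/`"none"`) and `matched_event`
#'   (earliest triggering readmission date, `NA` otherwise).
#' @export
label_windows <- function(windows, events, observation, horizon = 30) {
  stopifnot(horizon >= 1)
  missing_pat <- setdiff(unique(windows$patient_id), observation$patient_id)
  if (length(missing_pat) > 0) {
    stop("patients absent from observation table: ",
         paste(missing_pat, collapse = ", "), call. = FALSE)
  }
  obs_end <- observation$end[match(windows$patient_id,
                                   observation$patient_id)]
  validity <- ifelse(windows$last_day + horizon <= obs_end,
                     "valid", "invalid")
  label <- rep("none", nrow(windows))
  matched <- as.Date(rep(NA, nrow(windows)))
  for (i in seq_len(nrow(windows))) {
    if (validity[i] != "valid") next
    ev <- events$readmission_date[events$patient_id == windows$patient_id[i]]
    hit <- ev[ev > windows$last_day[i] &
                ev <= windows$last_day[i] + horizon]
    if (length(hit) > 0) {
      label[i] <- "positive"
      matched[i] <- min(hit)
    } else {
      label[i] <- "negative"
    }
  }
  windows$validity <- validity
  windows$label <- label
  windows$matched_event <- matched
  windows
}

# Feature vector layout: per-day block repeated for each of the 7 window
# days, then cross-window aggregates.
per_day_features <- c("ai_sum", "ai_mean", "ai_median", "ai_cov", "ri", "qoa")
aggregate_features <- c("agg_ai_sum_mean", "agg_ai_sum_cov", "agg_ri_mean",
                        "agg_qoa_mean", "agg_ai_sum_slope", "agg_qoa_slope")

#' Turn windows into model feature vectors
#'
#' For each window the feature vector holds, for each of its 7 days, the
#' daily quantities (`ai_sum`, `ai_mean`, `ai_median`, `ai_cov`, RI with 0
#' substituted when undefined, `qoa`) — 42 values — followed by 6
#' cross-window aggregates: mean and CoV of the daily AI sums, mean RI, mean
#' QoA, and the least-squares linear trend slopes (per day) of the daily AI
#' sum and of QoA, which carry the retrospective pre-readmission decline.
#' 48 features in total. Features are returned raw; standardization happens
#' inside cross-validation using training-fold statistics only.
#'
#' @param windows Window table from [build_windows()] (labelled or not).
#' @param daily The daily-features table the windows were built from.
#' @param window_length Days per window (default 7).
#' @return Numeric matrix, one row per window, named columns.
#' @export
featurize_windows <- function(windows, daily, window_length = 7) {
  day_names <- as.vector(vapply(seq_len(window_length), function(d) {
    paste0("d", d, "_", per_day_features)
  }, character(length(per_day_features))))
  feat_names <- c(day_names, aggregate_features)
  X <- matrix(NA_real_, nrow = nrow(windows), ncol = length(feat_names),
              dimnames = list(NULL, feat_names))
  if (nrow(windows) == 0) return(X)
  key <- paste(daily$patient_id, daily$date)
  xd <- seq_len(window_length) - mean(seq_len(window_length))
  sxx <- sum(xd^2)
  for (i in seq_len(nrow(windows))) {
    days <- windows$first_day[i] + 0:(window_length - 1)
    idx <- match(paste(windows$patient_id[i], days), key)
    if (anyNA(idx)) {
      stop("window day missing from daily-features table", call. = FALSE)
    }
    dd <- daily[idx, , drop = FALSE]
    ri0 <- ifelse(is.na(dd$ri), 0, dd$ri)
    per_day <- rbind(dd$ai_sum, dd$ai_mean, dd$ai_median, dd$ai_cov,
                     ri0, dd$qoa)
    m_ai <- mean(dd$ai_sum)
    cov_ai <- if (m_ai == 0) 0 else stats::sd(dd$ai_sum) / m_ai
    X[i, ] <- c(
      as.vector(per_day),
      m_ai,
      cov_ai,
      mean(ri0),
      mean(dd$qoa),
      sum(xd * dd$ai_sum) / sxx,
      sum(xd * dd$qoa) / sxx
    )
  }
  X
}

#' Blocked fold assignment for overlapping time-series windows
#'
#' Assigns windows to `k` cross-validation folds such that no calendar day of
#' any patient is shared between two folds (blocked cross-validation).
#' Windows are first grouped into time blocks: windows of one patient whose
#' last days are closer than `window_length` days share days and must stay
#' together. If fewer blocks than folds exist, the largest blocks are split
#' at interior points with a guard gap of `window_length - 1` days (6 days
#' for 7-day windows, the minimum making blocks day-disjoint); windows
#' falling inside a guard gap are excluded from cross-validation (`NA` fold).
#' Blocks are then dealt to folds in seeded random order, round-robin, so
#' fold sizes are balanced to within one block.
#'
#' @param windows Window table (any data.frame with `patient_id`,
#'   `last_day`).
#' @param k Number of folds (at least 2).
#' @param window_length Days per window (default 7).
#' @param seed Seed for the block-to-fold shuffle.
#' @return Integer vector of fold ids (1..k) aligned to `windows` rows; `NA`
#'   marks guard-gap windows excluded to prevent leakage.
#' @export
split_folds <- function(windows, k = 10, window_length = 7, seed = 1) {
  if (k < 2) stop("`k` must be at least 2", call. = FALSE)
  n <- nrow(windows)
  if (n == 0) return(integer(0))
  ord <- order(windows$patient_id, windows$last_day)
  pid <- windows$patient_id[ord]
  ld <- as.integer(windows$last_day[ord])
  # initial blocks: maximal groups of day-sharing windows
  new_block <- c(TRUE, pid[-1] != pid[-n] |
                   (ld[-1] - ld[-n]) >= window_length)
  blocks <- split(seq_len(n), cumsum(new_block))
  blocks <- unname(blocks)
  dropped <- integer(0)
  # split largest blocks (with guard gap) until k blocks exist
  while (length(blocks) < k) {
    sizes <- vapply(blocks, length, integer(1))
    split_done <- FALSE
    for (b in order(sizes, decreasing = TRUE)) {
      blk <- blocks[[b]]
      if (length(blk) < 2) next
      bd <- ld[blk]
      m <- ceiling(length(blk) / 2)
      j <- which(bd >= bd[m] + window_length)
      if (length(j) == 0 || m == length(blk)) next
      a_part <- blk[seq_len(m)]
      b_part <- blk[j]
      dropped <- c(dropped, setdiff(blk, c(a_part, b_part)))
      blocks[[b]] <- a_part
      blocks[[length(blocks) + 1]] <- b_part
      split_done <- TRUE
      break
    }
    if (!split_done) {
      stop("cannot separate the windows into ", k,
           " day-disjoint time blocks", call. = FALSE)
    }
  }
  set.seed(as.integer(seed))
  perm <- sample.int(length(blocks))
  fold <- rep(NA_integer_, n)
  for (i in seq_along(perm)) {
    fold[blocks[[perm[i]]]] <- ((i - 1L) %% k) + 1L
  }
  fold[dropped] <- NA_integer_
  out <- rep(NA_integer_, n)
  out[ord] <- fold
  out
}
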