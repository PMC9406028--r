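#' Prediction-based scoring: TP, FP and prediction accuracy
#'
#' Every valid window carries a yes/no predicted readmission. A predicted
#' readmission is a true prediction (TP) when the window's label is positive
#' (an actual readmission followed within the horizon) and a false
#' prediction (FP) otherwise. Prediction accuracy is `100 * TP / (TP + FP)`
#' and is undefined (`NA`) when nothing was predicted.
#'
#' @param predicted Logical vector: predicted readmission per valid window.
#' @param label Character vector of window labels, `"positive"` or
#'   `"negative"` (an `"invalid"`/`"none"` entry is an error: invalid
#'   windows must not be scored).
#' @return List with `tp`, `fp`, `accuracy` (percent).
#' @export
#' @examples
#' score_predictions(c(TRUE, TRUE, FALSE),
#'                   c("positive", "negative", "positive"))
score_predictions <- function(predicted, label) {
  stopifnot(length(predicted) == length(label), is.logical(predicted))
  if (!all(label %in% c("positive", "negative"))) {
    stop("predictions supplied for non-adjudicable (invalid) windows",
         call. = FALSE)
  }
  tp <- sum(predicted & label == "positive")
  fp <- sum(predicted & label == "negative")
  acc <- if (tp + fp == 0) NA_real_ else 100 * tp / (tp + fp)
  list(tp = tp, fp = fp, accuracy = acc)
}

#' Event-based scoring: TE, ME and event precision
#'
#' An actual readmission is a truly predicted event (TE) when at least one
#' window predicted a readmission in the 30 days prior to it — i.e. a
#' predicting window whose last day lies in `[event - horizon, event - 1]`;
#' a prediction dated the event day itself is not "prior". Otherwise it is a
#' mispredicted event (ME). Event-based precision is
#' `100 * TE / (TE + ME)`, undefined (`NA`) with zero events.
#'
#' @param predictions Data.frame of valid windows with `patient_id`,
#'   `last_day` (Date) and logical `predicted`.
#' @param events Event log (`patient_id, readmission_date`).
#' @param horizon Days of lookback (default 30).
#' @return List with `te`, `me`, `precision` (percent) and `per_event`, a
#'   data.frame `patient_id, event_date, truly_predicted, earliest_window`.
#' @export
score_events <- function(predictions, events, horizon = 30) {
  stopifnot(is.logical(predictions$predicted))
  n_ev <- nrow(events)
  truly <- logical(n_ev)
  earliest <- as.Date(rep(NA, n_ev))
  for (i in seq_len(n_ev)) {
    e <- events$readmission_date[i]
    w <- predictions[predictions$patient_id == events$patient_id[i] &
                       predictions$predicted &
                       predictions$last_day >= e - horizon &
                       predictions$last_day <= e - 1, , drop = FALSE]
    if (nrow(w) > 0) {
      truly[i] <- TRUE
      earliest[i] <- min(w$last_day)
    }
  }
  te <- sum(truly)
  me <- n_ev - te
  list(
    te = te, me = me,
    precision = if (n_ev == 0) NA_real_ else 100 * te / n_ev,
    per_event = data.frame(
      patient_id = events$patient_id,
      event_date = events$readmission_date,
      truly_predicted = truly,
      earliest_window = earliest
    )
  )
}

#' Assemble the dual evaluation report
#'
#' Combines prediction-based (TP/FP, prediction accuracy and its complement
#' the false-prediction rate) and event-based (TE/ME, event precision and
#' its complement the missed-event rate) statistics into one validated
#' report. Counts can be supplied directly (e.g. from an external run) or
#' computed from labelled predictions and an event log via
#' [evaluate_predictions()].
#'
#' @param n_valid Number of valid windows evaluated.
#' @param n_predicted Number of windows with a predicted readmission.
#' @param tp,fp Window-level true / false predictions; must sum to
#'   `n_predicted`.
#' @param te,me Event-level truly predicted / mispredicted counts.
#' @param n_windows Optional total window count (valid + invalid).
#' @param n_events Optional cross-check: number of actual readmissions
#'   adjudicated; an error is raised when `te + me` disagrees (e.g. events
#'   present but both counts zero).
#' @param per_event,per_window Optional provenance detail tables.
#' @return An object of class `readmission_report`: the counts plus
#'   `accuracy_prediction_based`, `false_prediction_rate`,
#'   `precision_event_based` and `missed_event_rate`, all in percent and
#'   `NA` when their denominator is zero. Percentages are stored at full
#'   precision; `print()` shows two decimals.
#' @export
#' @examples
#' r <- readmission_report(n_valid = 1361, n_predicted = 199,
#'                         tp = 140, fp = 59, te = 15, me = 6)
#' round(r$accuracy_prediction_based, 2)  # 70.35
readmission_report <- function(n_valid, n_predicted, tp, fp, te, me,
                               n_windows = NA_integer_, n_events = NULL,
                               per_event = NULL, per_window = NULL) {
  stopifnot(n_valid >= 0, n_predicted >= 0, tp >= 0, fp >= 0,
            te >= 0, me >= 0)
  if (tp + fp != n_predicted) {
    stop("inconsistent counts: tp + fp must equal n_predicted ",
         "(", tp, " + ", fp, " != ", n_predicted, ")", call. = FALSE)
  }
  if (n_predicted > n_valid) {
    stop("more predictions than valid windows", call. = FALSE)
  }
  if (!is.null(n_events) && te + me != n_events) {
    stop("inconsistent counts: te + me must equal the number of ",
         "adjudicated events (", te, " + ", me, " != ", n_events, ")",
         call. = FALSE)
  }
  n_events <- te + me
  if (!is.null(per_event) && nrow(per_event) != n_events) {
    stop("per-event detail does not match te + me", call. = FALSE)
  }
  acc <- if (n_predicted == 0) NA_real_ else 100 * tp / n_predicted
  prec <- if (n_events == 0) NA_real_ else 100 * te / n_events
  structure(
    list(
      n_windows = n_windows, n_valid = n_valid, n_predicted = n_predicted,
      tp = tp, fp = fp,
      accuracy_prediction_based = acc,
      false_prediction_rate = if (is.na(acc)) NA_real_ else 100 - acc,
      n_events = n_events, te = te, me = me,
      precision_event_based = prec,
      missed_event_rate = if (is.na(prec)) NA_real_ else 100 - prec,
      per_event = per_event, per_window = per_window
    ),
    class = "readmission_report"
  )
}

#' @export
print.readmission_report <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", v)
  cat("30-day readmission evaluation\n")
  if (!is.na(x$n_windows)) cat("  windows (total):     ", x$n_windows, "\n")
  cat("  valid windows:       ", x$n_valid, "\n")
  cat("  predicted windows:   ", x$n_predicted, "\n")
  cat("  TP / FP:             ", x$tp, "/", x$fp, "\n")
  cat("  prediction accuracy: ", pct(x$accuracy_prediction_based), "\n")
  cat("  false prediction:    ", pct(x$false_prediction_rate), "\n")
  cat("  events:              ", x$n_events, "\n")
  cat("  TE / ME:             ", x$te, "/", x$me, "\n")
  cat("  event precision:     ", pct(x$precision_event_based), "\n")
  cat("  missed events:       ", pct(x$missed_event_rate), "\n")
  invisible(x)
}

#' Evaluate labelled window predictions against the event log
#'
#' Runs both scoring views on the valid windows of a labelled prediction
#' table and assembles a consistent [readmission_report()], with per-window
#' and per-event provenance attached.
#'
#' @param windows Labelled window table ([label_windows()]) with an added
#'   logical `predicted` column (predictions are only read from valid
#'   windows).
#' @param events Event log (`patient_id, readmission_date`).
#' @param horizon Horizon in days (default 30).
#' @return A `readmission_report`.
#' @export
evaluate_predictions <- function(windows, events, horizon = 30) {
  stopifnot("predicted" %in% names(windows))
  valid <- windows[windows$validity == "valid", , drop = FALSE]
  sp <- score_predictions(valid$predicted, valid$label)
  se <- score_events(valid[, c("patient_id", "last_day", "predicted")],
                     events, horizon)
  readmission_report(
    n_valid = nrow(valid),
    n_predicted = sum(valid$predicted),
    tp = sp$tp, fp = sp$fp, te = se$te, me = se$me,
    n_windows = nrow(windows),
    per_event = se$per_event,
    per_window = data.frame(
      patient_id = valid$patient_id,
      last_day = valid$last_day,
      predicted = valid$predicted,
      outcome = valid$label
    )
  )
}

#' Permutation null for event-based precision
#'
#' Distribution of event-based precision when the same number of predicted
#' windows is placed uniformly at random among the valid windows — the null
#' of no association between predictions and readmissions. Used to check
#' that a trained classifier carries real signal: its observed event
#' precision should exceed the upper tail of this null.
#'
#' @param predictions Data.frame of valid windows with `patient_id`,
#'   `last_day`, logical `predicted`.
#' @param events Event log.
#' @param horizon Days of lookback (default 30).
#' @param n_perm Number of permutations (default 200).
#' @param seed RNG seed.
#' @return Numeric vector of `n_perm` null precisions (percent; `NA` when a
#'   permutation predicts nothing, which can only happen if none were
#'   predicted originally).
#' @export
permutation_null_precision <- function(predictions, events, horizon = 30,
                                       n_perm = 200, seed = 1) {
  set.seed(as.integer(seed))
  n <- nrow(predictions)
  vapply(seq_len(n_perm), function(i) {
    perm <- predictions
    perm$predicted <- predictions$predicted[sample.int(n)]
    score_events(perm, events, horizon)$precision
  }, numeric(1))
}
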