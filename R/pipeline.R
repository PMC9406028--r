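#' Configuration for a full pipeline run
#'
#' Bundles every tunable of the analysis in one place: the synthetic-cohort
#' configuration, the feature options, the windowing rules and the model
#' hyperparameters. Every constant the method needs lives here, never
#' hard-coded downstream, so `run_pipeline(run_config())` works with zero
#' arguments and alternatives stay testable.
#'
#' @param cohort A [cohort_config()].
#' @param min_wear_hours Wear-validity threshold (hours per day).
#' @param max_gap_hours Maximum single in-day recording gap (hours; `Inf`
#'   for the cumulative-coverage rule).
#' @param window_length Days per sliding window.
#' @param horizon Readmission lookahead/lookback horizon in days.
#' @param k Cross-validation folds.
#' @param learning_rate,n_epochs,tol SGD hyperparameters.
#' @param threshold Decision threshold on the readmission probability
#'   (inclusive).
#' @param class_weights Optional `c(w0, w1)` per-class gradient weights.
#' @param seed Master seed for fold assignment and training.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       min_wear_hours = 16, max_gap_hours = Inf,
                       window_length = 7, horizon = 30, k = 10,
                       learning_rate = 0.01, n_epochs = 200, tol = 1e-6,
                       threshold = 0.5, class_weights = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"),
            window_length >= 2, horizon >= 1, k >= 2,
            threshold > 0, threshold < 1,
            learning_rate >= 0, n_epochs >= 1)
  structure(
    list(cohort = cohort, min_wear_hours = min_wear_hours,
         max_gap_hours = max_gap_hours, window_length = window_length,
         horizon = horizon, k = as.integer(k),
         learning_rate = learning_rate, n_epochs = as.integer(n_epochs),
         tol = tol, threshold = threshold, class_weights = class_weights,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the complete readmission-prediction pipeline
#'
#' Simulate a cohort, extract daily activity features, build and label
#' sliding 7-day windows, assign blocked cross-validation folds, train the
#' SGD logistic-regression classifier, predict every valid window with the
#' averaged final model, and evaluate with the dual prediction-based /
#' event-based statistics. Fully deterministic for a fixed configuration.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, all stage artifacts are
#'   written there (daily features, events, labelled windows with fold ids,
#'   model JSON, predictions, report JSON, config JSON).
#' @return Invisibly, a list with `cohort`, `windows` (labelled, with
#'   `fold`, `probability`, `predicted` columns), `features` (matrix),
#'   `cv` (fold scores and models), `model`, and `report`
#'   (a [readmission_report()]).
#' @export
#' @examples
#' cfg <- run_config(cohort = cohort_config(n_patients = 4,
#'                                          days_per_patient = 90))
#' res <- run_pipeline(cfg)
#' res$report
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  cohort <- simulate_cohort(config$cohort, output = "daily")
  win <- build_windows(cohort$daily, cohort$events,
                       window_length = config$window_length)
  win <- label_windows(win, cohort$events, cohort$observation,
                       horizon = config$horizon)
  X <- featurize_windows(win, cohort$daily,
                         window_length = config$window_length)
  valid <- win$validity == "valid"
  fold <- rep(NA_integer_, nrow(win))
  fold[valid] <- split_folds(win[valid, , drop = FALSE], k = config$k,
                             window_length = config$window_length,
                             seed = config$seed)
  win$fold <- fold
  y <- as.integer(win$label == "positive")
  cv <- cross_validate(X[valid, , drop = FALSE], y[valid], fold[valid],
                       learning_rate = config$learning_rate,
                       n_epochs = config$n_epochs, tol = config$tol,
                       threshold = config$threshold, seed = config$seed,
                       class_weights = config$class_weights)
  pred <- predict_readmission(cv$model, X[valid, , drop = FALSE])
  win$probability <- NA_real_
  win$predicted <- NA
  win$probability[valid] <- pred$probability
  win$predicted[valid] <- pred$predicted
  report <- evaluate_predictions(win, cohort$events,
                                 horizon = config$horizon)
  res <- list(cohort = cohort, windows = win, features = X, cv = cv,
              model = cv$model, report = report)
  if (!is.null(out_dir)) write_run(res, config, out_dir)
  invisible(res)
}

#' @keywords internal
#' Write all pipeline artifacts as plain-text files.
write_run <- function(res, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(res$cohort$daily,
                     file.path(out_dir, "daily_features.csv"))
  data.table::fwrite(res$cohort$events, file.path(out_dir, "events.csv"))
  wout <- res$windows
  data.table::fwrite(wout, file.path(out_dir, "windows.csv"))
  fm <- data.frame(res$features, check.names = FALSE)
  data.table::fwrite(fm, file.path(out_dir, "features.csv"))
  write_model(res$model, file.path(out_dir, "model.json"))
  data.table::fwrite(res$cv$fold_scores,
                     file.path(out_dir, "cv_scores.csv"))
  rep <- res$report
  jsonlite::write_json(
    list(
      n_windows = rep$n_windows, n_valid = rep$n_valid,
      n_predicted = rep$n_predicted, tp = rep$tp, fp = rep$fp,
      accuracy_prediction_based = rep$accuracy_prediction_based,
      false_prediction_rate = rep$false_prediction_rate,
      n_events = rep$n_events, te = rep$te, me = rep$me,
      precision_event_based = rep$precision_event_based,
      missed_event_rate = rep$missed_event_rate
    ),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  cfg <- config
  cfg$cohort$observation_start <- as.character(cfg$cohort$observation_start)
  cfg$cohort <- unclass(cfg$cohort)
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(out_dir)
}
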