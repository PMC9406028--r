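#' Numerically stable logistic sigmoid
#'
#' `sigmoid(x) = 1 / (1 + exp(-x))`, computed without overflow for large
#' `|x|`. Vectorized.
#'
#' @param x Real input(s).
#' @return Probabilities in `(0, 1)` (reaching 0/1 only by floating-point
#'   underflow).
#' @export
#' @examples
#' sigmoid(0)  # 0.5
sigmoid <- function(x) {
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  e <- exp(x[!pos])
  out[!pos] <- e / (1 + e)
  out
}

#' Construct a logistic-regression model object
#'
#' @param weights Numeric weight vector (one per feature).
#' @param bias Intercept.
#' @param threshold Probability cut-off for declaring a predicted
#'   readmission; the cut is inclusive (`probability >= threshold`).
#' @param learning_rate SGD step size alpha.
#' @param standardization List with numeric `center` and `scale` vectors
#'   applied to features before the linear score (identity by default).
#' @param feature_names Optional feature names.
#' @return An object of class `logistic_model`.
#' @export
logistic_model <- function(weights, bias = 0, threshold = 0.5,
                           learning_rate = 0.01,
                           standardization = NULL, feature_names = NULL) {
  weights <- as.numeric(weights)
  stopifnot(all(is.finite(weights)), is.finite(bias),
            threshold > 0, threshold < 1, learning_rate >= 0)
  if (is.null(standardization)) {
    standardization <- list(center = rep(0, length(weights)),
                            scale = rep(1, length(weights)))
  }
  stopifnot(length(standardization$center) == length(weights),
            length(standardization$scale) == length(weights),
            all(standardization$scale > 0))
  structure(
    list(weights = weights, bias = bias, threshold = threshold,
         learning_rate = learning_rate, standardization = standardization,
         feature_names = feature_names),
    class = "logistic_model"
  )
}

#' One stochastic-gradient-descent update
#'
#' With prediction `yhat = sigmoid(w . x + b)`, each weight is updated as
#' `w_i <- w_i - alpha * (yhat - y) * x_i` and the bias as
#' `b <- b - alpha * (yhat - y)`. The input `x` is taken as already on the
#' model's feature scale (no standardization is applied here).
#'
#' @param model A [logistic_model()].
#' @param x Feature vector.
#' @param y Observed class, 0 or 1.
#' @return The updated model.
#' @export
sgd_step <- function(model, x, y) {
  stopifnot(inherits(model, "logistic_model"),
            length(x) == length(model$weights), y %in% c(0, 1))
  if (anyNA(x) || !all(is.finite(x))) {
    stop("non-finite value in feature vector", call. = FALSE)
  }
  yhat <- sigmoid(sum(model$weights * x) + model$bias)
  g <- yhat - y
  model$weights <- model$weights - model$learning_rate * g * x
  model$bias <- model$bias - model$learning_rate * g
  model
}

log_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train logistic regression by stochastic gradient descent
#'
#' Weights start from seeded small random values; examples are reshuffled
#' every epoch; training stops after `n_epochs` epochs or as soon as the
#' epoch-mean log-loss improves by less than `tol`.
#'
#' @param X Numeric feature matrix (rows = examples), already on the scale
#'   the model will see (standardize first if desired).
#' @param y 0/1 outcome vector; both classes must be present.
#' @param learning_rate SGD step size alpha.
#' @param n_epochs Maximum passes over the data.
#' @param tol Log-loss improvement below which training stops.
#' @param threshold Decision threshold stored in the returned model.
#' @param seed RNG seed for initialization and shuffling.
#' @param class_weights Optional length-2 vector `c(w0, w1)` multiplying the
#'   gradient of negative/positive examples (off, i.e. `c(1, 1)`, by
#'   default).
#' @return A fitted [logistic_model()] with attributes `n_epochs_run` and
#'   `final_log_loss`.
#' @export
train_logistic <- function(X, y, learning_rate = 0.01, n_epochs = 200,
                           tol = 1e-6, threshold = 0.5, seed = 1,
                           class_weights = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) {
    stop("training set must contain both classes", call. = FALSE)
  }
  if (anyNA(X) || !all(is.finite(X))) {
    stop("non-finite value in feature matrix", call. = FALSE)
  }
  n <- nrow(X)
  p <- ncol(X)
  cw <- if (is.null(class_weights)) c(1, 1) else class_weights
  wvec <- cw[y + 1]
  set.seed(as.integer(seed))
  w <- stats::rnorm(p, 0, 0.01)
  b <- stats::rnorm(1, 0, 0.01)
  Xt <- t(X)
  alpha <- learning_rate
  prev_ll <- Inf
  ep_run <- 0L
  for (ep in seq_len(n_epochs)) {
    ord <- sample.int(n)
    for (j in ord) {
      xj <- Xt[, j]
      z <- sum(w * xj) + b
      yh <- if (z >= 0) 1 / (1 + exp(-z)) else {e <- exp(z); e / (1 + e)}
      g <- alpha * (yh - y[j]) * wvec[j]
      w <- w - g * xj
      b <- b - g
    }
    ep_run <- ep
    ll <- log_loss(sigmoid(drop(X %*% w) + b), y)
    if (is.finite(prev_ll) && abs(prev_ll - ll) < tol) break
    prev_ll <- ll
  }
  m <- logistic_model(w, b, threshold = threshold,
                      learning_rate = learning_rate,
                      feature_names = colnames(X))
  attr(m, "n_epochs_run") <- ep_run
  attr(m, "final_log_loss") <- log_loss(sigmoid(drop(X %*% w) + b), y)
  m
}

standardization_stats <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_standardization <- function(X, std) {
  sweep(sweep(X, 2, std$center, "-"), 2, std$scale, "/")
}

#' Blocked k-fold cross-validation with an averaged final model
#'
#' For each fold: features are standardized using training-fold statistics
#' only, a model is trained on the remaining folds, and log-loss plus
#' classification accuracy are scored on the held-out fold. The final model
#' is the element-wise mean of the per-fold weights and biases, carrying a
#' pooled standardization computed over all cross-validated rows.
#'
#' @param X Feature matrix (raw scale).
#' @param y 0/1 outcomes.
#' @param folds Integer fold ids from [split_folds()]; `NA` rows are
#'   excluded.
#' @param learning_rate,n_epochs,tol,threshold,seed,class_weights Passed to
#'   [train_logistic()]; every fold trains from the same seed so that
#'   identical fold data give identical fold scores.
#' @return A list with `fold_scores` (data.frame
#'   `fold, n_train, n_val, log_loss, accuracy`), `fold_models`, and
#'   `model`, the averaged [logistic_model()].
#' @export
cross_validate <- function(X, y, folds, learning_rate = 0.01,
                           n_epochs = 200, tol = 1e-6, threshold = 0.5,
                           seed = 1, class_weights = NULL) {
  X <- as.matrix(X)
  keep <- !is.na(folds)
  X <- X[keep, , drop = FALSE]
  y <- as.numeric(y)[keep]
  folds <- folds[keep]
  ids <- sort(unique(folds))
  if (length(ids) < 2) stop("need at least 2 folds", call. = FALSE)
  scores <- vector("list", length(ids))
  models <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    f <- ids[i]
    tr <- folds != f
    if (!any(tr) || !any(!tr)) stop("empty fold", call. = FALSE)
    std <- standardization_stats(X[tr, , drop = FALSE])
    Xtr <- apply_standardization(X[tr, , drop = FALSE], std)
    Xva <- apply_standardization(X[!tr, , drop = FALSE], std)
    m <- train_logistic(Xtr, y[tr], learning_rate = learning_rate,
                        n_epochs = n_epochs, tol = tol,
                        threshold = threshold, seed = seed,
                        class_weights = class_weights)
    pv <- sigmoid(drop(Xva %*% m$weights) + m$bias)
    scores[[i]] <- data.frame(
      fold = f, n_train = sum(tr), n_val = sum(!tr),
      log_loss = log_loss(pv, y[!tr]),
      accuracy = mean((pv >= threshold) == (y[!tr] == 1))
    )
    models[[i]] <- m
  }
  W <- do.call(rbind, lapply(models, `[[`, "weights"))
  pooled <- standardization_stats(X)
  avg <- logistic_model(
    colMeans(W),
    bias = mean(vapply(models, `[[`, numeric(1), "bias")),
    threshold = threshold, learning_rate = learning_rate,
    standardization = pooled, feature_names = colnames(X)
  )
  list(fold_scores = do.call(rbind, scores), fold_models = models,
       model = avg)
}

#' Predict readmission from feature vectors
#'
#' Applies the model's stored standardization, computes the readmission
#' probability through the sigmoid, and declares a predicted readmission
#' when the probability reaches the decision threshold (inclusive).
#'
#' @param model A [logistic_model()].
#' @param X Feature matrix or single feature vector on the raw scale.
#' @return Data.frame with `probability` and logical `predicted`.
#' @export
predict_readmission <- function(model, X) {
  stopifnot(inherits(model, "logistic_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != length(model$weights)) {
    stop("feature dimension mismatch: model has ", length(model$weights),
         ", input has ", ncol(X), call. = FALSE)
  }
  Xs <- apply_standardization(X, model$standardization)
  p <- sigmoid(drop(Xs %*% model$weights) + model$bias)
  data.frame(probability = p, predicted = p >= model$threshold)
}

#' Serialize / restore a logistic model as JSON
#'
#' @param model A [logistic_model()].
#' @param path Output (input) JSON path.
#' @return `write_model` invisibly returns `path`; `read_model` returns the
#'   restored [logistic_model()].
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "logistic_model"))
  obj <- list(
    schema = "pareadmit-logistic-model/1",
    weights = model$weights,
    bias = model$bias,
    threshold = model$threshold,
    learning_rate = model$learning_rate,
    standardization = model$standardization,
    feature_names = model$feature_names
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "pareadmit-logistic-model/1")) {
    stop("unrecognized model schema in ", path, call. = FALSE)
  }
  logistic_model(obj$weights, obj$bias, threshold = obj$threshold,
                 learning_rate = obj$learning_rate,
                 standardization = obj$standardization,
                 feature_names = obj$feature_names)
}
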