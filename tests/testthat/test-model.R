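test_that("sigmoid is symmetric, bounded and overflow-free", {
  expect_equal(sigmoid(0), 0.5)
  x <- c(-20, -3, -0.5, 0.1, 2, 15)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, length(x)))
  expect_equal(sigmoid(710), 1)          # no overflow for large input
  expect_gte(sigmoid(710), 1 - 1e-300)
  expect_equal(sigmoid(-710), 0)         # underflow, not NaN
  expect_true(all(sigmoid(c(-1e6, 1e6)) >= 0 & sigmoid(c(-1e6, 1e6)) <= 1))
})

test_that("one SGD step matches the printed update rule", {
  m <- logistic_model(weights = c(0, 0), bias = 0, learning_rate = 0.1)
  m2 <- sgd_step(m, c(1, 0), 1)
  # yhat = sigmoid(0) = 0.5; w' = w - 0.1*(0.5-1)*x; b' = b - 0.1*(0.5-1)
  expect_equal(m2$weights, c(0.05, 0))
  expect_equal(m2$bias, 0.05)
  # a second step on the same example strictly improves its prediction
  p1 <- predict_readmission(m2, c(1, 0))$probability
  m3 <- sgd_step(m2, c(1, 0), 1)
  p2 <- predict_readmission(m3, c(1, 0))$probability
  expect_gt(p2, p1)
  expect_error(sgd_step(m, c(NaN, 0), 1), "non-finite")
})

test_that("the SGD step equals a numerical log-loss gradient step", {
  set.seed(42)
  for (i in 1:20) {
    p <- sample(2:6, 1)
    w <- rnorm(p); b <- rnorm(1); x <- rnorm(p); y <- sample(0:1, 1)
    alpha <- 0.05
    m <- logistic_model(w, b, learning_rate = alpha)
    m2 <- sgd_step(m, x, y)
    loss <- function(wb) {
      z <- sum(wb[1:p] * x) + wb[p + 1]
      pr <- 1 / (1 + exp(-z))
      -(y * log(pr) + (1 - y) * log(1 - pr))
    }
    h <- 1e-6
    wb <- c(w, b)
    num_grad <- vapply(seq_len(p + 1), function(j) {
      e <- rep(0, p + 1); e[j] <- h
      (loss(wb + e) - loss(wb - e)) / (2 * h)
    }, numeric(1))
    expect_equal(c(m2$weights, m2$bias), wb - alpha * num_grad,
                 tolerance = 1e-6)
  }
})

test_that("training separates a linearly separable toy set", {
  X <- rbind(c(0, 0), c(0, 1), c(2, 2), c(2, 3))
  y <- c(0, 0, 1, 1)
  m <- train_logistic(X, y, learning_rate = 0.5, n_epochs = 500, tol = 0,
                      seed = 1)
  pred <- predict_readmission(m, X)
  expect_equal(as.numeric(pred$predicted), y)
  expect_error(train_logistic(X, c(1, 1, 1, 1)), "both classes")
})

test_that("a zero learning rate leaves the seeded initialization intact", {
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(c(0, 1), 10)
  m <- train_logistic(X, y, learning_rate = 0, n_epochs = 5, seed = 9)
  set.seed(9)
  expect_equal(m$weights, rnorm(2, 0, 0.01))
  expect_equal(m$bias, rnorm(1, 0, 0.01))
})

test_that("training is deterministic under a fixed seed", {
  set.seed(77)
  X <- matrix(rnorm(200), 100, 2)
  y <- as.integer(runif(100) < sigmoid(X %*% c(1, -1)))
  m1 <- train_logistic(X, y, seed = 5)
  m2 <- train_logistic(X, y, seed = 5)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$bias, m2$bias)
  m3 <- train_logistic(X, y, seed = 6)
  expect_false(identical(m1$weights, m3$weights))
})

test_that("SGD recovers known generating coefficients", {
  true_w <- c(2, -1); true_b <- 0.5
  for (s in 1:3) {
    set.seed(1000 + s)
    X <- matrix(rnorm(2000 * 2), ncol = 2)
    y <- as.integer(runif(2000) < sigmoid(drop(X %*% true_w) + true_b))
    m <- train_logistic(X, y, learning_rate = 0.01, n_epochs = 200,
                        seed = s)
    expect_lt(max(abs(c(m$weights - true_w, m$bias - true_b))), 0.3)
    # independent oracle: the maximum-likelihood fit lands in the same place
    glm_fit <- suppressWarnings(
      stats::glm(y ~ X, family = stats::binomial()))
    expect_equal(unname(m$weights), unname(coef(glm_fit)[2:3]),
                 tolerance = 0.15)
  }
})

test_that("estimation bias shrinks as the sample grows", {
  true_w <- c(2, -1); true_b <- 0.5
  err <- vapply(c(500, 2000, 8000), function(n) {
    set.seed(n)
    X <- matrix(rnorm(n * 2), ncol = 2)
    y <- as.integer(runif(n) < sigmoid(drop(X %*% true_w) + true_b))
    m <- train_logistic(X, y, learning_rate = 0.005, n_epochs = 100,
                        seed = 1)
    max(abs(c(m$weights - true_w, m$bias - true_b)))
  }, numeric(1))
  expect_lt(err[3], 0.2)
  expect_lt(err[3], err[1])
})

test_that("cross-validation scores folds and averages their models", {
  # identical data in every fold -> every fold score identical
  X1 <- rbind(c(0, 0), c(0, 1), c(2, 2), c(2, 3))
  y1 <- c(0, 0, 1, 1)
  X <- do.call(rbind, replicate(3, X1, simplify = FALSE))
  y <- rep(y1, 3)
  folds <- rep(1:3, each = 4)
  cv <- cross_validate(X, y, folds, learning_rate = 0.5, n_epochs = 300,
                       tol = 0, seed = 1)
  expect_equal(cv$fold_scores$accuracy, rep(1, 3))  # separable case
  expect_equal(cv$fold_scores$log_loss,
               rep(cv$fold_scores$log_loss[1], 3), tolerance = 1e-9)
  # averaging identical fold models reproduces their weights
  W <- do.call(rbind, lapply(cv$fold_models, `[[`, "weights"))
  expect_equal(cv$model$weights, colMeans(W))
  same <- lapply(cv$fold_models, function(m) {
    m$weights <- cv$fold_models[[1]]$weights
    m$bias <- cv$fold_models[[1]]$bias
    m
  })
  Wsame <- do.call(rbind, lapply(same, `[[`, "weights"))
  expect_equal(colMeans(Wsame), cv$fold_models[[1]]$weights)
  expect_error(cross_validate(X, y, rep(1, 12)), "folds")
})

test_that("prediction applies the threshold inclusively and monotonically", {
  m <- logistic_model(c(0, 0), bias = 0)
  p <- predict_readmission(m, rbind(c(10, -3), c(0, 0)))
  expect_equal(p$probability, c(0.5, 0.5))
  expect_true(all(p$predicted))  # probability 0.5 at threshold 0.5 predicts
  m <- logistic_model(c(1, 2), bias = -0.5)
  xs <- seq(-3, 3, length.out = 25)
  probs <- predict_readmission(m, cbind(xs, xs))$probability
  expect_true(all(diff(probs) > 0))
  expect_error(predict_readmission(m, c(1, 2, 3)), "dimension")
})

test_that("models survive a JSON round trip", {
  m <- logistic_model(c(0.3, -1.2, 0), bias = 0.7, threshold = 0.4,
                      standardization = list(center = c(1, 2, 3),
                                             scale = c(1, 0.5, 2)),
                      feature_names = c("a", "b", "c"))
  f <- withr::local_tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- read_model(f)
  expect_equal(m2$weights, m$weights)
  expect_equal(m2$bias, m$bias)
  expect_equal(m2$threshold, m$threshold)
  expect_equal(m2$standardization$scale, m$standardization$scale)
  expect_equal(m2$feature_names, m$feature_names)
  x <- c(0.5, 1.5, 4)
  expect_equal(predict_readmission(m2, x), predict_readmission(m, x))
})
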