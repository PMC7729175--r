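test_that("RLDA recovers the analytic solutions at the gamma extremes", {
  # symmetric 1-D classes: boundary at 0
  set.seed(20)
  x <- matrix(c(rnorm(50, 1, 0.5), rnorm(50, -1, 0.5)), ncol = 1)
  y <- rep(c("target", "non-target"), each = 50)
  m0 <- fit_rlda(x, y, gamma = 0)
  boundary <- -m0$bias / m0$weights
  expect_lt(abs(boundary - (mean(x[1:50]) + mean(x[51:100])) / 2), 1e-10)

  # gamma = 1: nearest-mean rule, direction proportional to mean difference
  set.seed(21)
  X <- matrix(rnorm(200 * 3), 200, 3)
  yy <- rep(c(TRUE, FALSE), each = 100)
  X[yy, ] <- X[yy, ] + c(1, 2, -1)
  m1 <- fit_rlda(X, yy, gamma = 1)
  dm <- colMeans(X[yy, ]) - colMeans(X[!yy, ])
  cosine <- sum(m1$weights * dm) / sqrt(sum(m1$weights^2) * sum(dm^2))
  expect_lt(abs(cosine - 1), 1e-10)

  # gamma = 0 on a well-conditioned fixture: matches the explicit formula
  set.seed(22)
  X2 <- matrix(rnorm(400 * 2), 400, 2) %*% matrix(c(1, 0.4, 0.4, 1), 2)
  y2 <- rep(c(TRUE, FALSE), each = 200)
  X2[y2, ] <- X2[y2, ] + c(1.5, 0.5)
  fit <- fit_rlda(X2, y2, gamma = 0)
  oracle <- lda_oracle(X2, y2)
  expect_lt(max(abs(fit$weights - oracle$weights)), 1e-8)
  expect_lt(abs(fit$bias - oracle$bias), 1e-8)
})

test_that("classification thresholds the affine score at zero", {
  set.seed(23)
  X <- matrix(rnorm(300 * 4), 300, 4)
  y <- rep(c(TRUE, FALSE), each = 150)
  X[y, 2] <- X[y, 2] + 2.5
  model <- fit_rlda(X, y)
  expect_equal(classify_epochs(model$class_means$target, model), "target")
  expect_equal(classify_epochs(model$class_means$`non-target`, model),
               "non-target")

  sim <- matrix(rnorm(1000 * 4), 1000, 4)
  scores <- as.vector(sim %*% model$weights + model$bias)
  expect_equal(classify_epochs(sim, model),
               ifelse(scores >= 0, "target", "non-target"))

  expect_bmi_error(classify_epochs(matrix(0, 1, 2), model),
                   "bmi_shape_error")
  expect_bmi_error(fit_rlda(X, rep(TRUE, 300)), "bmi_estimation_error")
  expect_bmi_error(fit_rlda(X, y, gamma = 1.2), "bmi_parameter_error")
})

test_that("stepwise selection finds a planted separating feature", {
  fx <- planted_features(n_per_class = 60, p = 21, informative = 7,
                         separation = 6)  # classes essentially separable
  model <- stepwise_select_and_fit(fx$X, fx$labels)
  expect_true(fx$informative %in% model$selected)
  expect_gte(crossval(fx$X, fx$labels, seed = 5)$acc_weighted, 95)
})

test_that("stepwise on permuted labels stays at chance level", {
  fx <- planted_features(n_per_class = 60, p = 21)
  set.seed(31)
  accs <- replicate(20, {
    y_perm <- sample(fx$labels)
    tryCatch(
      crossval(fx$X, y_perm, seed = 3)$acc_weighted,
      bmi_error = function(e) 50)
  })
  expect_lt(abs(mean(accs) - 50), 6)
})

test_that("the final stepwise model dominates every single-feature model", {
  set.seed(32)
  X <- matrix(rnorm(200 * 6), 200, 6)
  y <- rep(c(TRUE, FALSE), each = 100)
  X[y, 1] <- X[y, 1] + 1.2
  X[y, 4] <- X[y, 4] + 0.8
  cfg <- stepwise_config()
  model <- stepwise_select_and_fit(X, y, cfg)
  folds <- p300bmi:::fold_machinery(X, y, cfg$n_folds, cfg$seed)
  final_score <- p300bmi:::cv_score_subset(folds, model$selected,
                                           cfg$gamma)[["weighted"]]
  for (j in 1:6) {
    single <- p300bmi:::cv_score_subset(folds, j, cfg$gamma)[["weighted"]]
    expect_gte(final_score, single)
  }
})

test_that("stepwise terminates, ignores duplicates, and beats the empty model", {
  fx <- planted_features(n_per_class = 50, p = 15, informative = 4)
  cfg <- stepwise_config(max_features = 60)
  model <- stepwise_select_and_fit(fx$X, fx$labels, cfg)
  expect_lte(model$n_steps, 2 * cfg$max_features)

  # duplicating a candidate column: the pair is never selected together
  X_dup <- cbind(fx$X, fx$X[, fx$informative])
  dup_id <- ncol(X_dup)
  model2 <- stepwise_select_and_fit(X_dup, fx$labels, cfg)
  expect_false(all(c(fx$informative, dup_id) %in% model2$selected))

  # weighted training accuracy of the returned model is above chance
  pred <- classify_epochs(fx$X, model)
  acc_t <- mean(pred[fx$labels == "target"] == "target")
  acc_nt <- mean(pred[fx$labels == "non-target"] == "non-target")
  expect_gte(0.5 * (acc_t + acc_nt), 0.5)
})

test_that("pure-noise candidates that cannot beat the empty model are an error", {
  # two interchangeable constant features carry no class information
  set.seed(33)
  X <- matrix(1, 60, 2)
  y <- rep(c(TRUE, FALSE), each = 30)
  expect_bmi_error(stepwise_select_and_fit(X, y), "bmi_estimation_error")
})

test_that("classifier models serialize to JSON and back", {
  fx <- planted_features()
  model <- stepwise_select_and_fit(fx$X, fx$labels)
  f <- tempfile(fileext = ".json")
  write_classifier(model, f)
  back <- read_classifier(f)
  expect_equal(back$selected, model$selected)
  expect_equal(back$weights, model$weights, tolerance = 1e-12)
  expect_equal(back$bias, model$bias, tolerance = 1e-12)
  expect_equal(classify_epochs(fx$X, back), classify_epochs(fx$X, model))
})
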