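test_that("search spaces match their published bounds", {
  rf <- rf_search_space()
  expect_equal(nrow(rf), 4)
  expect_equal(rf$lower, c(50, 3, 2, 1))
  expect_equal(rf$upper, c(500, 30, 20, 10))
  expect_true(all(rf$kind == "integer"))

  xg <- xgb_search_space()
  expect_equal(nrow(xg), 5)
  expect_equal(xg$name, c("n_estimators", "max_depth", "learning_rate",
                          "gamma", "min_child_weight"))
  expect_equal(xg[xg$name == "learning_rate", ]$lower, 0.01)
  expect_equal(xg[xg$name == "learning_rate", ]$upper, 0.3)
  expect_equal(xg[xg$name == "gamma", ]$lower, 0)
  expect_equal(xg$kind, c("integer", "integer", "continuous", "continuous",
                          "integer"))
})

test_that("cross-validated fitness is zero on separable data and satisfies its identity", {
  train <- make_blobs(n0 = 60, n1 = 60, sep = 6, seed = 2)
  fr <- cv_fitness(list(n_estimators = 100, max_depth = 10,
                        min_samples_split = 2, min_samples_leaf = 1),
                   "random_forest", train, k = 5, seed = 1)
  expect_equal(fr$fitness, 0)
  expect_length(fr$fold_accuracy, 5)
  expect_true(all(fr$fold_accuracy >= 0 & fr$fold_accuracy <= 1))
  expect_identical(fr$fitness + mean(fr$fold_accuracy), 1)

  # identity also away from the boundary
  noisy <- make_noise_cohort(n = 120, prevalence = 0.4, seed = 3)
  fr2 <- cv_fitness(list(), "logistic_regression", noisy, k = 4, seed = 2,
                    smote = FALSE)
  expect_identical(fr2$fitness + mean(fr2$fold_accuracy), 1)

  single <- make_noise_cohort(n = 40, prevalence = 0.025, seed = 1)  # 1 event
  expect_error(cv_fitness(list(), "logistic_regression", single, k = 2,
                          seed = 1, smote = FALSE), "single outcome class")
})

test_that("null-data fitness approximates the minority fraction", {
  fits <- vapply(1:20, function(s) {
    noise <- make_noise_cohort(n = 200, prevalence = 0.1, p = 2, seed = 100 + s)
    cv_fitness(list(), "logistic_regression", noise, k = 5, seed = s,
               smote = FALSE)$fitness
  }, numeric(1))
  expect_lt(abs(mean(fits) - 0.10), 0.03)
})

test_that("SSA tuning never loses to the warm-start default configuration", {
  train <- make_blobs(n0 = 70, n1 = 25, sep = 1.2, p = 3, seed = 5)
  default_rf <- list(n_estimators = 100, max_depth = 15,
                     min_samples_split = 2, min_samples_leaf = 1)
  f_default <- cv_fitness(default_rf, "random_forest", train, k = 3,
                          seed = 11)$fitness
  tm <- tune_model(train, "random_forest", n_salps = 3, n_iter = 2,
                   seed = 11, k = 3, warm_start = default_rf)
  expect_lte(tm$fitness, f_default)
  # decoded assignment lies within the published bounds
  rf <- rf_search_space()
  for (j in seq_len(nrow(rf))) {
    v <- tm$assignment[[rf$name[j]]]
    expect_gte(v, rf$lower[j]); expect_lte(v, rf$upper[j])
  }
  expect_equal(nrow(tm$trace), 2)
  expect_s3_class(tm$model, "clin_model")
  expect_equal(glance(tm)$family, "random_forest")
})

test_that("fold-validation rows never enter their fold's SMOTE pool", {
  # structural check on the fold assignment: each row is held out exactly once
  y <- rep(c(0L, 1L), c(90, 30))
  fold <- salpclinrisk:::stratified_folds(y, 5, seed = 2)
  expect_equal(sort(unique(fold)), 1:5)
  for (f in 1:5) {
    expect_length(intersect(which(fold == f), which(fold != f)), 0)
  }
  # stratification: each fold carries its share of events
  per_fold <- table(fold[y == 1])
  expect_true(all(per_fold == 6))
})

test_that("the baseline zoo fits all eight families deterministically", {
  train <- make_blobs(n0 = 50, n1 = 50, sep = 2, seed = 9)
  zoo <- baseline_zoo(train, seed = 3)
  expect_length(zoo, 8)
  expect_setequal(names(zoo), model_families())
  test <- make_blobs(n0 = 20, n1 = 20, sep = 2, seed = 10)
  for (nm in names(zoo)) {
    p <- predict_prob(zoo[[nm]], test)
    expect_true(all(p >= 0 & p <= 1), info = nm)
    expect_length(p, 40)
  }
  zoo2 <- baseline_zoo(train, seed = 3)
  for (nm in names(zoo)) {
    expect_identical(predict_prob(zoo[[nm]], test),
                     predict_prob(zoo2[[nm]], test), info = nm)
  }
})

test_that("tuning improves or ties the baseline across synthetic cohorts", {
  wins <- 0L
  for (s in 1:6) {
    train <- make_blobs(n0 = 60, n1 = 20, sep = 1, p = 3, seed = 200 + s)
    default_rf <- list(n_estimators = 100, max_depth = 15,
                       min_samples_split = 2, min_samples_leaf = 1)
    f0 <- cv_fitness(default_rf, "random_forest", train, k = 3,
                     seed = s)$fitness
    tm <- tune_model(train, "random_forest", n_salps = 3, n_iter = 2,
                     seed = s, k = 3, warm_start = default_rf)
    wins <- wins + (tm$fitness <= f0)
  }
  expect_equal(wins, 6L)
})
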