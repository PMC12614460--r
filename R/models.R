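#' Model families available in the zoo
#'
#' @return Character vector of the eight supported family names.
#' @export
model_families <- function() {
  c("random_forest", "xgboost", "logistic_regression", "svm", "knn",
    "decision_tree", "mlp", "gaussian_nb")
}

#' Fit a single classifier family
#'
#' Uniform wrapper over the underlying libraries: random forest via
#' \pkg{ranger} (probability forest), gradient boosting via \pkg{xgboost},
#' logistic regression via [stats::glm()], SVM with Platt-scaled
#' probabilities and Gaussian naive Bayes via \pkg{e1071}, k-nearest
#' neighbors via \pkg{class}, CART via \pkg{rpart} and a single-hidden-layer
#' perceptron via \pkg{nnet}. Hyperparameter names follow the tuned search
#' spaces (`n_estimators`, `max_depth`, `min_samples_split`,
#' `min_samples_leaf`, `learning_rate`, `gamma`, `min_child_weight`);
#' anything unspecified stays at the library default.
#'
#' @param train Complete tibble with a binary 0/1 outcome column.
#' @param family One of [model_families()].
#' @param params Named list of hyperparameters (may be empty).
#' @param seed Integer seed; fits are deterministic given the seed.
#' @param outcome Outcome column name.
#' @return A `clin_model` object supporting [predict_prob()].
#' @export
fit_model <- function(train, family, params = list(), seed = 1,
                      outcome = "rupture") {
  family <- match.arg(family, model_families())
  feat <- setdiff(names(train), outcome)
  x <- as.matrix(train[, feat, drop = FALSE])
  y <- as.integer(train[[outcome]])
  df <- data.frame(x, .y = factor(y, levels = c(0, 1)), check.names = FALSE)

  fit <- withr::with_seed(seed, switch(
    family,
    random_forest = {
      md <- params$max_depth %||% 0  # 0 = unlimited in ranger
      ranger::ranger(
        x = train[, feat, drop = FALSE], y = factor(y, levels = c(0, 1)),
        num.trees = params$n_estimators %||% 500,
        max.depth = md,
        min.node.size = params$min_samples_split %||% NULL,
        min.bucket = params$min_samples_leaf %||% NULL,
        probability = TRUE, num.threads = 1, seed = seed)
    },
    xgboost = {
      dtr <- xgboost::xgb.DMatrix(x, label = y)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$max_depth %||% 6,
                      eta = params$learning_rate %||% 0.3,
                      gamma = params$gamma %||% 0,
                      min_child_weight = params$min_child_weight %||% 1,
                      nthread = 1, seed = seed),
        data = dtr, nrounds = params$n_estimators %||% 100, verbose = 0)
    },
    logistic_regression = suppressWarnings(
      stats::glm(.y ~ ., data = df, family = stats::binomial())),
    svm = e1071::svm(.y ~ ., data = df, probability = TRUE,
                     kernel = params$kernel %||% "radial",
                     cost = params$cost %||% 1),
    knn = list(x = x, y = y, k = params$k %||% 5),  # lazy learner
    decision_tree = rpart::rpart(.y ~ ., data = df, method = "class"),
    mlp = suppressWarnings(nnet::nnet(
      .y ~ ., data = df, size = params$size %||% 8,
      decay = params$decay %||% 1e-3, maxit = params$maxit %||% 200,
      trace = FALSE)),
    gaussian_nb = e1071::naiveBayes(.y ~ ., data = df)
  ))

  structure(list(family = family, fit = fit, features = feat,
                 params = params, seed = seed, outcome = outcome),
            class = "clin_model")
}

#' Predicted probability of the positive class
#'
#' @param object A `clin_model`.
#' @param newdata Tibble/data frame containing the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict_prob <- function(object, newdata, ...) {
  UseMethod("predict_prob")
}

#' @export
predict_prob.clin_model <- function(object, newdata, ...) {
  miss <- setdiff(object$features, names(newdata))
  if (length(miss)) {
    stop("Feature set mismatch; missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  nd <- newdata[, object$features, drop = FALSE]
  xm <- as.matrix(nd)
  dfn <- data.frame(nd, check.names = FALSE)
  p <- switch(
    object$family,
    random_forest = stats::predict(object$fit, data = nd,
                                   num.threads = 1)$predictions[, "1"],
    xgboost = stats::predict(object$fit, xgboost::xgb.DMatrix(xm)),
    logistic_regression = suppressWarnings(
      stats::predict(object$fit, newdata = dfn, type = "response")),
    svm = {
      pr <- stats::predict(object$fit, newdata = dfn, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    knn = withr::with_seed(object$seed, {
      pred <- class::knn(object$fit$x, xm,
                         cl = factor(object$fit$y, levels = c(0, 1)),
                         k = object$fit$k, prob = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "1", win, 1 - win)
    }),
    decision_tree = stats::predict(object$fit, newdata = dfn,
                                   type = "prob")[, "1"],
    mlp = as.numeric(stats::predict(object$fit, newdata = dfn,
                                    type = "raw")),
    gaussian_nb = stats::predict(object$fit, newdata = dfn,
                                 type = "raw")[, "1"]
  )
  unname(pmin(pmax(as.numeric(p), 0), 1))
}

#' @export
print.clin_model <- function(x, ...) {
  cat("<clin_model> family:", x$family, " features:", length(x$features), "\n")
  invisible(x)
}
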