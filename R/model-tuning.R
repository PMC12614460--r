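#' Random-forest hyperparameter search space
#'
#' Four integer dimensions: `n_estimators` in \[50, 500\], `max_depth` in
#' \[3, 30\], `min_samples_split` in \[2, 20\], `min_samples_leaf` in
#' \[1, 10\].
#'
#' @return A `search_space`.
#' @export
rf_search_space <- function() {
  search_space(
    name = c("n_estimators", "max_depth", "min_samples_split", "min_samples_leaf"),
    lower = c(50, 3, 2, 1),
    upper = c(500, 30, 20, 10),
    kind = "integer")
}

#' XGBoost hyperparameter search space
#'
#' Five dimensions: integer `n_estimators` in \[50, 500\], integer
#' `max_depth` in \[3, 15\], continuous `learning_rate` in \[0.01, 0.3\],
#' continuous `gamma` in \[0, 1\], integer `min_child_weight` in \[1, 10\].
#'
#' @return A `search_space`.
#' @export
xgb_search_space <- function() {
  search_space(
    name = c("n_estimators", "max_depth", "learning_rate", "gamma",
             "min_child_weight"),
    lower = c(50, 3, 0.01, 0, 1),
    upper = c(500, 15, 0.3, 1, 10),
    kind = c("integer", "integer", "continuous", "continuous", "integer"))
}

# Stratified K-fold assignment: per class, shuffle then deal round-robin.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (lev in unique(y)) {
      idx <- sample(which(y == lev))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Cross-validated error-rate fitness
#'
#' The quantity the swarm minimizes: `1 - mean(fold accuracies)` under
#' stratified K-fold cross-validation of the training partition. Within each
#' fold, SMOTE rebalancing is applied to the fold-training part only (the
#' fold-validation rows never enter the oversampling neighbor pool), the
#' model is fitted there and scored at threshold 0.5 on the untouched
#' fold-validation part.
#'
#' @param assignment Named hyperparameter list for `family`.
#' @param family Model family (see [model_families()]).
#' @param train Complete, labeled training tibble.
#' @param k Number of folds (default 5).
#' @param seed Integer seed (folds, SMOTE and fits).
#' @param smote Apply fold-internal SMOTE (default `TRUE`).
#' @param k_neighbors SMOTE neighbor count.
#' @param outcome Outcome column name.
#' @return A `fitness_result`: list with `fold_accuracy` (length `k`) and
#'   `fitness` (`= 1 - mean(fold_accuracy)` exactly).
#' @export
cv_fitness <- function(assignment, family, train, k = 5, seed = 1,
                       smote = TRUE, k_neighbors = 5, outcome = "rupture") {
  if (k < 2) stop("`k` must be at least 2.", call. = FALSE)
  y <- as.integer(train[[outcome]])
  fold <- stratified_folds(y, k, seed)
  acc <- vapply(seq_len(k), function(f) {
    tr <- train[fold != f, , drop = FALSE]
    va <- train[fold == f, , drop = FALSE]
    if (length(unique(tr[[outcome]])) < 2) {
      stop("Fold ", f, " has a single outcome class in its training part.",
           call. = FALSE)
    }
    if (smote) tr <- apply_smote(tr, k_neighbors = k_neighbors,
                                 seed = seed + f, outcome = outcome)
    m <- fit_model(tr, family, params = assignment, seed = seed + f,
                   outcome = outcome)
    p <- predict_prob(m, va)
    mean(as.integer(p >= 0.5) == va[[outcome]])
  }, numeric(1))
  structure(list(fold_accuracy = acc, fitness = 1 - mean(acc)),
            class = "fitness_result")
}

#' SSA-tune a random forest or XGBoost model
#'
#' Runs the salp swarm over the family's search space with the
#' cross-validated error-rate fitness, then refits the decoded best
#' assignment on the full (SMOTE-rebalanced) training partition.
#'
#' @param train Complete training tibble.
#' @param family `"random_forest"` or `"xgboost"`.
#' @param n_salps,n_iter Swarm budget (defaults 20 and 50).
#' @param seed Integer seed.
#' @param k CV folds for the fitness (default 5).
#' @param warm_start Optional named list of hyperparameters used as the
#'   leader's starting position (e.g. library defaults).
#' @param smote Fold-internal SMOTE in the fitness, and final-fit SMOTE.
#' @param outcome Outcome column name.
#' @return A `tuned_model`: list with the fitted `model` (a `clin_model`),
#'   `assignment`, `fitness`, `trace` tibble and the underlying `ssa_result`.
#' @export
tune_model <- function(train, family = c("random_forest", "xgboost"),
                       n_salps = 20, n_iter = 50, seed = 1, k = 5,
                       warm_start = NULL, smote = TRUE, outcome = "rupture") {
  family <- match.arg(family)
  space <- if (family == "random_forest") rf_search_space() else xgb_search_space()
  fitness <- function(pos) {
    cv_fitness(decode_position(pos, space), family, train, k = k, seed = seed,
               smote = smote, outcome = outcome)$fitness
  }
  leader_init <- NULL
  if (!is.null(warm_start)) {
    leader_init <- vapply(space$name, function(nm) {
      as.numeric(warm_start[[nm]] %||% stop("warm_start missing '", nm, "'.",
                                            call. = FALSE))
    }, numeric(1))
  }
  ssa <- ssa_optimize(fitness, space, n_salps = n_salps, n_iter = n_iter,
                      seed = seed, leader_init = leader_init)
  final_train <- if (smote) apply_smote(train, seed = seed, outcome = outcome) else train
  model <- fit_model(final_train, family, params = ssa$best_assignment,
                     seed = seed, outcome = outcome)
  structure(list(family = family, model = model,
                 assignment = ssa$best_assignment,
                 fitness = ssa$best_fitness, trace = ssa$trace, ssa = ssa,
                 seed = seed),
            class = "tuned_model")
}

#' @export
print.tuned_model <- function(x, ...) {
  cat("<tuned_model> family:", x$family, " CV fitness:",
      signif(x$fitness, 6), "\n")
  print(tibble::as_tibble(lapply(x$assignment, identity)))
  invisible(x)
}

#' Tidy a tuned model into its convergence trace
#'
#' @param x A `tuned_model`.
#' @param ... Unused.
#' @return Tibble with `iteration` and `best_fitness`.
#' @export
tidy.tuned_model <- function(x, ...) x$trace

#' One-row summary of a tuned model
#'
#' @param x A `tuned_model`.
#' @param ... Unused.
#' @return One-row tibble with family, tuned hyperparameters and CV fitness.
#' @export
glance.tuned_model <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(family = x$family, fitness = x$fitness),
                   tibble::as_tibble(lapply(x$assignment, identity)))
}

#' @export
autoplot.tuned_model <- function(object, ...) {
  autoplot.ssa_result(object$ssa) +
    ggplot2::labs(subtitle = paste0("SSA-", object$family,
                                    " (1 - CV accuracy)"))
}

#' Fit the baseline model zoo
#'
#' Fits all eight classifier families at library-default hyperparameters with
#' a fixed seed. SVM probabilities are Platt-calibrated; the perceptron
#' outputs sigmoid probabilities directly.
#'
#' @param train Complete training tibble (typically SMOTE-rebalanced).
#' @param seed Integer seed.
#' @param families Subset of [model_families()] to fit.
#' @param outcome Outcome column name.
#' @return Named list of `clin_model` objects.
#' @export
baseline_zoo <- function(train, seed = 1, families = model_families(),
                         outcome = "rupture") {
  families <- match.arg(families, model_families(), several.ok = TRUE)
  stats::setNames(
    lapply(families, function(fam) fit_model(train, fam, seed = seed,
                                             outcome = outcome)),
    families)
}
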