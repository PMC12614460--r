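#' Stratified three-way cohort split
#'
#' Partitions the cohort into train / validation / test row-index sets,
#' stratified on the outcome. Sizes within each outcome class follow the
#' largest-remainder allocation of `n_class * fractions`, which reproduces the
#' published 495 / 124 / 155 partition of 774 patients at (0.64, 0.16, 0.20)
#' and keeps every partition's event prevalence within one case of the global
#' prevalence.
#'
#' @param cohort Cohort tibble with an outcome column.
#' @param fractions Length-3 numeric vector (train, validation, test) summing
#'   to 1 (tolerance 1e-9).
#' @param seed Integer seed; the split is identical across runs for a fixed
#'   seed.
#' @param outcome Name of the binary outcome column.
#' @return An object of class `split_indices`: a list with integer index
#'   vectors `train`, `validation`, `test` (pairwise disjoint, jointly
#'   exhaustive).
#' @export
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' sp <- split_cohort(cohort, seed = 1)
#' lengths(sp)
split_cohort <- function(cohort, fractions = c(0.64, 0.16, 0.20), seed = 1,
                         outcome = "rupture") {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9) {
    stop("`fractions` must be three numbers that sum to 1 (tolerance 1e-9).",
         call. = FALSE)
  }
  y <- cohort[[outcome]]
  if (is.null(y)) stop("Outcome column '", outcome, "' not found.", call. = FALSE)
  if (sum(y == 1) < 3) stop("Need at least 3 events to stratify.", call. = FALSE)

  out <- list(train = integer(), validation = integer(), test = integer())
  withr::with_seed(seed, {
    for (lev in sort(unique(y))) {
      idx <- sample(which(y == lev))
      sizes <- largest_remainder(length(idx), fractions)
      cut1 <- sizes[1]; cut2 <- sizes[1] + sizes[2]
      out$train <- c(out$train, idx[seq_len(cut1)])
      out$validation <- c(out$validation, idx[seq_len(cut2)[-seq_len(cut1)]])
      out$test <- c(out$test, idx[-seq_len(cut2)])
    }
  })
  out <- lapply(out, sort)
  structure(out, class = "split_indices", n = nrow(cohort), seed = seed,
            fractions = fractions)
}

#' @export
print.split_indices <- function(x, ...) {
  cat("<split_indices> train:", length(x$train),
      " validation:", length(x$validation),
      " test:", length(x$test), "\n")
  invisible(x)
}

#' Tidy a split into a row/partition table
#'
#' @param x A `split_indices` object.
#' @param ... Unused.
#' @return A tibble with columns `row` and `partition`.
#' @export
tidy.split_indices <- function(x, ...) {
  tibble::tibble(
    row = c(x$train, x$validation, x$test),
    partition = rep(c("train", "validation", "test"), lengths(x))
  ) |> dplyr::arrange(.data$row)
}

#' Chained-equation imputation
#'
#' Fills missing cells by iterated per-variable regression on all other
#' variables (multiple imputation by chained equations, returning a single
#' completed dataset): continuous variables by linear regression with a
#' residual-scale noise draw, binary variables by logistic regression with a
#' Bernoulli draw. Missing cells are initialized at the observed column mean
#' (binary: observed majority) and the chain sweeps the incomplete columns, in
#' order of increasing missingness, for `n_cycles` cycles. Observed cells are
#' never modified.
#'
#' @param data Tibble of one cohort partition (the outcome column, if present,
#'   is used as a predictor but never imputed-over since it is complete).
#' @param n_cycles Number of chained sweeps (default 10).
#' @param seed Integer seed for the noise draws.
#' @return Completed tibble, same shape, no `NA` cells.
#' @export
impute_chained <- function(data, n_cycles = 10, seed = 1) {
  if (!anyNA(data)) return(data)
  zero_obs <- vapply(data, function(x) all(is.na(x)), logical(1))
  if (any(zero_obs)) {
    stop("Column(s) with zero observed values cannot be imputed: ",
         paste(names(data)[zero_obs], collapse = ", "), call. = FALSE)
  }
  if (!any(!vapply(data, anyNA, logical(1)))) {
    stop("Need at least one fully observed column.", call. = FALSE)
  }

  miss_mask <- lapply(data, is.na)
  n_miss <- vapply(miss_mask, sum, integer(1))
  targets <- names(sort(n_miss[n_miss > 0]))
  filled <- data
  # initialize: mean for continuous, observed majority for binary
  for (v in targets) {
    x <- filled[[v]]
    if (is_binary_col(x)) {
      maj <- as.numeric(names(which.max(table(x))))
      x[miss_mask[[v]]] <- maj
    } else {
      x[miss_mask[[v]]] <- mean(x, na.rm = TRUE)
    }
    filled[[v]] <- x
  }

  withr::with_seed(seed, {
    for (cycle in seq_len(n_cycles)) {
      for (v in targets) {
        m <- miss_mask[[v]]
        obs <- !m
        rhs <- filled[, setdiff(names(filled), v), drop = FALSE]
        df <- cbind(.y = filled[[v]], rhs)
        if (is_binary_col(data[[v]])) {
          fit <- suppressWarnings(
            stats::glm(.y ~ ., data = df[obs, , drop = FALSE],
                       family = stats::binomial()))
          p <- suppressWarnings(
            stats::predict(fit, newdata = df[m, , drop = FALSE],
                           type = "response"))
          filled[[v]][m] <- stats::rbinom(sum(m), 1, pmin(pmax(p, 0), 1))
        } else {
          fit <- suppressWarnings(stats::lm(.y ~ ., data = df[obs, , drop = FALSE]))
          mu <- suppressWarnings(
            stats::predict(fit, newdata = df[m, , drop = FALSE]))
          sigma <- sqrt(sum(stats::residuals(fit)^2) /
                          max(1, stats::df.residual(fit)))
          filled[[v]][m] <- mu + stats::rnorm(sum(m), 0, sigma)
        }
      }
    }
  })
  filled
}

#' Univariate feature screening
#'
#' Tests each candidate variable for association with the binary outcome and
#' flags those with p below `alpha` (default 0.05) for modeling. Continuous
#' variables: Shapiro-Wilk normality within each outcome group; if both groups
#' are compatible with normality (p > 0.05) a Welch t-test is used, otherwise
#' a Mann-Whitney U test. Binary variables: chi-square test, switching to
#' Fisher's exact test when any expected cell count is below 5. A constant
#' column is reported with p = 1 and a warning.
#'
#' @param train Complete training-partition tibble.
#' @param alpha Selection threshold on the p-value (default 0.05).
#' @param outcome Name of the binary outcome column.
#' @param top_k Optional integer: additionally keep only the `top_k` smallest
#'   p-values among the selected variables (the source analysis fed nine
#'   variables to its models).
#' @return A tibble with one row per variable: `variable`, `kind`, `test`
#'   ("t", "mann_whitney", "chi_square", "fisher" or "none"), `statistic`,
#'   `p_value`, `selected`.
#' @export
screen_features <- function(train, alpha = 0.05, outcome = "rupture",
                            top_k = NULL) {
  if (anyNA(train)) stop("`train` must be complete (impute first).", call. = FALSE)
  y <- train[[outcome]]
  vars <- setdiff(names(train), outcome)

  rows <- purrr::map(vars, function(v) {
    x <- train[[v]]
    if (length(unique(x)) < 2) {
      warning("Variable '", v, "' is constant; marked unselected.", call. = FALSE)
      return(tibble::tibble(variable = v,
                            kind = ifelse(is_binary_col(x), "binary", "continuous"),
                            test = "none", statistic = NA_real_, p_value = 1))
    }
    if (is_binary_col(x)) {
      tab <- table(factor(x, levels = c(0, 1)), factor(y, levels = c(0, 1)))
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        ft <- stats::fisher.test(tab)
        tibble::tibble(variable = v, kind = "binary", test = "fisher",
                       statistic = NA_real_, p_value = ft$p.value)
      } else {
        ct <- suppressWarnings(stats::chisq.test(tab))
        tibble::tibble(variable = v, kind = "binary", test = "chi_square",
                       statistic = unname(ct$statistic), p_value = ct$p.value)
      }
    } else {
      x0 <- x[y == 0]; x1 <- x[y == 1]
      normal <- vapply(list(x0, x1), function(g) {
        if (length(g) < 3 || length(g) > 5000 || length(unique(g)) < 2) return(FALSE)
        stats::shapiro.test(g)$p.value > 0.05
      }, logical(1))
      if (all(normal)) {
        tt <- stats::t.test(x0, x1)
        tibble::tibble(variable = v, kind = "continuous", test = "t",
                       statistic = unname(tt$statistic), p_value = tt$p.value)
      } else {
        wt <- suppressWarnings(stats::wilcox.test(x0, x1))
        tibble::tibble(variable = v, kind = "continuous", test = "mann_whitney",
                       statistic = unname(wt$statistic), p_value = wt$p.value)
      }
    }
  })
  res <- dplyr::bind_rows(rows)
  res$selected <- res$p_value < alpha
  if (!is.null(top_k)) {
    keep <- res$variable[res$selected][order(res$p_value[res$selected])]
    keep <- utils::head(keep, top_k)
    res$selected <- res$variable %in% keep
  }
  res
}

#' SMOTE minority oversampling
#'
#' Oversamples the minority class to parity with the majority by synthesizing
#' convex combinations `x + u * (x_nn - x)`, `u ~ U(0, 1)`, between a minority
#' row and one of its `k_neighbors` nearest minority neighbors (Euclidean
#' distance over the feature columns). Binary features of a synthetic row take
#' the value of the nearer parent (interpolation thresholded at 0.5). Original
#' rows are preserved; an already balanced table is returned unchanged.
#'
#' @param train Complete training tibble with a binary outcome column.
#' @param k_neighbors Number of nearest minority neighbors (default 5).
#' @param seed Integer seed.
#' @param outcome Name of the outcome column.
#' @return Tibble with the original rows followed by the synthetic minority
#'   rows; both classes have the majority count.
#' @export
apply_smote <- function(train, k_neighbors = 5, seed = 1, outcome = "rupture") {
  y <- train[[outcome]]
  counts <- table(factor(y, levels = sort(unique(y))))
  if (length(counts) < 2 || diff(range(counts)) == 0) return(train)
  minority <- as.numeric(names(which.min(counts)))
  n_min <- min(counts); n_needed <- max(counts) - n_min
  if (n_min <= k_neighbors) {
    stop("Minority count (", n_min, ") must exceed k_neighbors (", k_neighbors,
         ").", call. = FALSE)
  }
  feat <- setdiff(names(train), outcome)
  x_min <- as.matrix(train[y == minority, feat, drop = FALSE])
  binary_feat <- vapply(train[, feat, drop = FALSE], is_binary_col, logical(1))

  d <- as.matrix(stats::dist(x_min))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k_neighbors)]))

  withr::with_seed(seed, {
    base_idx <- sample(rep_len(seq_len(n_min), n_needed))
    nn_pick <- nn[cbind(base_idx, sample(k_neighbors, n_needed, replace = TRUE))]
    u <- stats::runif(n_needed)
    synth <- x_min[base_idx, , drop = FALSE] +
      u * (x_min[nn_pick, , drop = FALSE] - x_min[base_idx, , drop = FALSE])
    if (any(binary_feat)) {
      # nearer parent: u < 0.5 keeps the base row's value, else the neighbor's
      take_nn <- u >= 0.5
      synth[, binary_feat] <- ifelse(
        matrix(take_nn, nrow = n_needed, ncol = sum(binary_feat)),
        x_min[nn_pick, binary_feat, drop = FALSE],
        x_min[base_idx, binary_feat, drop = FALSE])
    }
  })
  synth_tb <- tibble::as_tibble(as.data.frame(synth))
  # preserve the outcome column's type (integer labels stay integer)
  synth_tb[[outcome]] <- rep(train[[outcome]][match(minority, y)], n_needed)
  synth_tb <- synth_tb[, names(train)]
  dplyr::bind_rows(train, synth_tb)
}

#' Train-fitted standardization
#'
#' Computes per-feature center (mean) and scale (standard deviation) from the
#' training partition only and applies them to every supplied partition, so
#' the transformed training columns have mean 0 and unit variance while
#' validation/test columns are transformed with the same, train-fitted
#' parameters (no leakage). A zero-variance column gets scale 1 with a
#' warning.
#'
#' @param train Training tibble (complete).
#' @param ... Further partitions to transform with the train-fitted
#'   parameters.
#' @param outcome Outcome column, excluded from scaling.
#' @return A list with `params` (tibble: `variable`, `center`, `scale`) and
#'   `partitions` (list of transformed tibbles; first element is the train
#'   partition).
#' @export
standardize <- function(train, ..., outcome = "rupture") {
  others <- list(...)
  feat <- setdiff(names(train), outcome)
  center <- vapply(train[feat], mean, numeric(1))
  scale <- vapply(train[feat], stats::sd, numeric(1))
  zero <- !is.finite(scale) | scale == 0
  if (any(zero)) {
    warning("Zero-variance column(s) scaled by 1: ",
            paste(feat[zero], collapse = ", "), call. = FALSE)
    scale[zero] <- 1
  }
  transform1 <- function(tb) {
    for (v in feat) tb[[v]] <- (tb[[v]] - center[[v]]) / scale[[v]]
    tb
  }
  list(
    params = tibble::tibble(variable = feat, center = unname(center),
                            scale = unname(scale)),
    partitions = lapply(c(list(train), others), transform1)
  )
}

#' Leakage audit of a pipeline split
#'
#' Asserts the structural leakage guard: the three partitions are pairwise
#' disjoint and exhaustive, and every index set consumed by a train-fitted
#' stage (screening, scaling, SMOTE) is contained in the training partition
#' and disjoint from the test partition.
#'
#' @param split A `split_indices` object.
#' @param stage_indices Named list of integer row-index vectors actually read
#'   by each train-fitted stage.
#' @return `TRUE` invisibly if the audit passes; otherwise an error naming the
#'   offending stage.
#' @export
audit_leakage <- function(split, stage_indices = list()) {
  all_idx <- sort(c(split$train, split$validation, split$test))
  if (!identical(all_idx, seq_len(attr(split, "n")))) {
    stop("Split is not a partition of the cohort rows.", call. = FALSE)
  }
  if (length(intersect(split$train, split$test)) ||
      length(intersect(split$train, split$validation)) ||
      length(intersect(split$validation, split$test))) {
    stop("Split partitions overlap.", call. = FALSE)
  }
  for (st in names(stage_indices)) {
    idx <- stage_indices[[st]]
    if (length(intersect(idx, split$test))) {
      stop("Stage '", st, "' read test-partition rows.", call. = FALSE)
    }
    if (length(setdiff(idx, split$train))) {
      stop("Stage '", st, "' read rows outside the training partition.",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}
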