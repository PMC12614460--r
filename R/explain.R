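#' Additive Shapley feature attributions
#'
#' Interventional Shapley values of a fitted classifier's predicted
#' probability: the value of a feature coalition is the model's mean
#' prediction over the background rows with the coalition's columns replaced
#' by the explained sample's values. With 12 or fewer features the full
#' coalition lattice is enumerated (exact Shapley); above that a
#' permutation-sampling estimator is used. Both satisfy additivity exactly:
#' `base + sum(attributions) = prediction` for every sample, because each
#' sampled permutation telescopes from the empty to the full coalition.
#'
#' @param model A `clin_model` (or `tuned_model`).
#' @param data Tibble of samples to explain (feature columns required).
#' @param background Tibble of reference rows (typically a training
#'   subsample); defaults to `data` itself.
#' @param n_perm Permutations for the sampling estimator (default 32).
#' @param seed Integer seed (permutation draws only).
#' @return An `attribution_set`: list with `attributions` (n x p matrix),
#'   `base` (mean background prediction), `prediction` (per-sample model
#'   output), `features`, and `ranking` (tibble ordered by decreasing mean
#'   absolute attribution).
#' @export
shapley_values <- function(model, data, background = NULL, n_perm = 32,
                           seed = 1) {
  if (inherits(model, "tuned_model")) model <- model$model
  if (!inherits(model, "clin_model")) {
    stop("`model` must be a fitted clin_model.", call. = FALSE)
  }
  feat <- model$features
  miss <- setdiff(feat, names(data))
  if (length(miss)) {
    stop("Feature set mismatch; data lacks: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  background <- background %||% data
  x <- as.matrix(data[, feat, drop = FALSE])
  bg <- as.matrix(background[, feat, drop = FALSE])
  p <- length(feat)
  predict_mat <- function(m) {
    predict_prob(model, tibble::as_tibble(as.data.frame(m))[, feat, drop = FALSE])
  }
  base <- mean(predict_mat(bg))

  phi <- withr::with_seed(seed, {
    if (p <= 12) {
      t(apply(x, 1, function(xi) shap_exact_one(xi, bg, p, predict_mat)))
    } else {
      perms <- replicate(n_perm, sample.int(p), simplify = FALSE)
      t(apply(x, 1, function(xi) shap_perm_one(xi, bg, p, perms, predict_mat)))
    }
  })
  if (p == 1) phi <- matrix(phi, ncol = 1)
  colnames(phi) <- feat
  pred <- predict_mat(x)
  ranking <- tibble::tibble(feature = feat,
                            mean_abs_attribution = colMeans(abs(phi))) |>
    dplyr::arrange(dplyr::desc(.data$mean_abs_attribution))
  structure(list(attributions = phi, base = base, prediction = pred,
                 features = feat, ranking = ranking),
            class = "attribution_set")
}

# Exact Shapley for one sample by full coalition enumeration.
shap_exact_one <- function(xi, bg, p, predict_mat) {
  n_mask <- 2L^p
  b <- nrow(bg)
  # coalition values: mean prediction over background with S's columns set to xi
  big <- bg[rep(seq_len(b), n_mask), , drop = FALSE]
  masks <- matrix(FALSE, n_mask, p)
  for (j in seq_len(p)) {
    masks[, j] <- bitwAnd(seq_len(n_mask) - 1L, bitwShiftL(1L, j - 1L)) > 0L
  }
  for (j in seq_len(p)) {
    rows <- rep(masks[, j], each = b)
    big[rows, j] <- xi[j]
  }
  v <- colMeans(matrix(predict_mat(big), nrow = b))
  sizes <- rowSums(masks)
  w <- exp(lfactorial(sizes) + lfactorial(p - sizes - 1) - lfactorial(p))
  phi <- numeric(p)
  for (j in seq_len(p)) {
    without <- !masks[, j]
    with_j <- which(without) + bitwShiftL(1L, j - 1L)  # mask index of S+{j}
    phi[j] <- sum(w[without] * (v[with_j] - v[without]))
  }
  phi
}

# Permutation-sampling Shapley for one sample; each permutation's marginal
# contributions telescope to f(x) - base, so additivity is exact.
shap_perm_one <- function(xi, bg, p, perms, predict_mat) {
  b <- nrow(bg)
  n_perm <- length(perms)
  # coalitions per permutation: empty, then cumulatively add features
  blocks <- lapply(perms, function(perm) {
    m <- bg[rep(seq_len(b), p + 1), , drop = FALSE]
    for (k in seq_len(p)) {
      cols <- perm[seq_len(k)]
      rows <- seq_len(b) + k * b
      m[rows, cols] <- matrix(xi[cols], nrow = b, ncol = k, byrow = TRUE)
    }
    m
  })
  v <- colMeans(matrix(predict_mat(do.call(rbind, blocks)), nrow = b))
  v <- matrix(v, nrow = p + 1)  # (p+1) coalition values per permutation
  phi <- numeric(p)
  for (j in seq_len(n_perm)) {
    gains <- diff(v[, j])
    phi[perms[[j]]] <- phi[perms[[j]]] + gains
  }
  phi / n_perm
}

#' @export
print.attribution_set <- function(x, ...) {
  cat("<attribution_set> ", nrow(x$attributions), " samples x ",
      length(x$features), " features; base ", signif(x$base, 4), "\n", sep = "")
  print(utils::head(x$ranking, 5))
  invisible(x)
}

#' Tidy attributions into a long sample/feature table
#'
#' @param x An `attribution_set`.
#' @param ... Unused.
#' @return Tibble with `sample`, `feature`, `attribution`.
#' @export
tidy.attribution_set <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$attributions)) |>
    dplyr::mutate(sample = dplyr::row_number(), .before = 1) |>
    tidyr::pivot_longer(-"sample", names_to = "feature",
                        values_to = "attribution")
}

#' Summary-style plot of global attributions
#'
#' @param object An `attribution_set`.
#' @param ... Unused.
#' @return A ggplot: per-feature attribution distributions, ordered by global
#'   importance.
#' @export
autoplot.attribution_set <- function(object, ...) {
  long <- tidy.attribution_set(object)
  long$feature <- factor(long$feature, levels = rev(object$ranking$feature))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$attribution, y = .data$feature)) +
    ggplot2::geom_vline(xintercept = 0, color = "grey60") +
    ggplot2::geom_jitter(height = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "Attribution (probability scale)", y = NULL,
                  title = "Global feature attributions") +
    ggplot2::theme_minimal()
}

#' Global feature attributions with importance ranking
#'
#' @inheritParams shapley_values
#' @return An `attribution_set` (see [shapley_values()]); its `ranking`
#'   element orders features by mean absolute attribution, descending.
#' @export
global_attributions <- function(model, data, background = NULL, n_perm = 32,
                                seed = 1) {
  shapley_values(model, data, background = background, n_perm = n_perm,
                 seed = seed)
}

#' Local explanation of a single sample
#'
#' Signed per-feature contributions whose sum, plus the base value, equals
#' the sample's predicted probability.
#'
#' @inheritParams shapley_values
#' @param sample One-row tibble with the model's feature columns.
#' @return Tibble ordered by decreasing absolute contribution: `feature`,
#'   `value`, `contribution`, plus attributes `base` and `prediction`.
#' @export
local_explanation <- function(model, sample, background = NULL, n_perm = 32,
                              seed = 1) {
  if (nrow(sample) != 1L) stop("`sample` must be a single row.", call. = FALSE)
  att <- shapley_values(model, sample, background = background,
                        n_perm = n_perm, seed = seed)
  out <- tibble::tibble(
    feature = att$features,
    value = as.numeric(sample[1, att$features]),
    contribution = as.numeric(att$attributions[1, ])) |>
    dplyr::arrange(dplyr::desc(abs(.data$contribution)))
  attr(out, "base") <- att$base
  attr(out, "prediction") <- att$prediction[1]
  out
}
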