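#' Confusion matrix at a threshold
#'
#' Predicts positive when `probabilities >= threshold` and tallies the counts
#' against the 0/1 labels.
#'
#' @param probabilities Numeric vector in \[0, 1\].
#' @param labels Binary 0/1 vector, same length.
#' @param threshold Decision threshold (default 0.5).
#' @return A one-row tibble with `tp`, `fp`, `fn`, `tn`, `threshold`
#'   (counts sum to `length(labels)`).
#' @export
#' @examples
#' confusion_at(c(0.9, 0.6, 0.4, 0.2), c(1, 1, 1, 0), 0.5)
confusion_at <- function(probabilities, labels, threshold = 0.5) {
  if (length(probabilities) != length(labels)) {
    stop("`probabilities` and `labels` must have the same length.", call. = FALSE)
  }
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE)) {
    stop("`probabilities` must lie in [0, 1].", call. = FALSE)
  }
  pred <- as.integer(probabilities >= threshold)
  tibble::tibble(
    tp = sum(pred == 1 & labels == 1),
    fp = sum(pred == 1 & labels == 0),
    fn = sum(pred == 0 & labels == 1),
    tn = sum(pred == 0 & labels == 0),
    threshold = threshold)
}

#' ROC area under the curve
#'
#' Trapezoidal integration of the ROC curve over the unique score values
#' (ties grouped into single threshold steps); numerically identical to the
#' rank/Mann-Whitney formulation with the midrank tie correction.
#'
#' @param probabilities Scores (any monotone scale).
#' @param labels Binary 0/1 vector.
#' @return AUC in \[0, 1\], or `NA` if one class is absent.
#' @export
roc_auc <- function(probabilities, labels) {
  pts <- roc_points(probabilities, labels)
  if (is.null(pts)) return(NA_real_)
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return Tibble with `threshold`, `fpr`, `tpr`, ordered from the (0, 0) to
#'   the (1, 1) corner, or `NULL` if one class is absent.
#' @export
roc_points <- function(probabilities, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NULL)
  thr <- sort(unique(probabilities), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(probabilities >= t & labels == 1), numeric(1))
  fp <- vapply(thr, function(t) sum(probabilities >= t & labels == 0), numeric(1))
  tibble::tibble(threshold = c(Inf, thr),
                 fpr = c(0, fp / n0),
                 tpr = c(0, tp / n1))
}

#' Precision-recall area under the curve
#'
#' Trapezoidal integration of precision over recall across the unique score
#' thresholds. For a random scorer this converges to the class prevalence.
#'
#' @inheritParams roc_auc
#' @return PR-AUC in \[0, 1\], or `NA` if there are no positives.
#' @export
pr_auc <- function(probabilities, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0) return(NA_real_)
  thr <- sort(unique(probabilities), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(probabilities >= t & labels == 1), numeric(1))
  pp <- vapply(thr, function(t) sum(probabilities >= t), numeric(1))
  recall <- tp / n1
  precision <- tp / pp
  # anchor the curve at the smallest observed recall with its precision
  r <- c(recall[1], recall)
  p <- c(precision[1], precision)
  sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' Full metrics report from a confusion matrix and scores
#'
#' Closed-form threshold metrics from the confusion counts plus
#' threshold-free ROC-AUC and PR-AUC from the scores. Metrics with a zero
#' denominator (e.g. precision with no predicted positives) are reported as
#' `NA`, never coerced to 0.
#'
#' @param cm One-row confusion tibble from [confusion_at()].
#' @param probabilities,labels The scores and labels the matrix was computed
#'   from (used for the AUCs; pass `NULL` to skip them).
#' @return One-row tibble: confusion counts, `accuracy`, `precision`,
#'   `recall`, `specificity`, `f1`, `roc_auc`, `pr_auc`, `threshold`.
#' @export
#' @examples
#' metrics_from(tibble::tibble(tp = 9, fp = 3, fn = 1, tn = 142,
#'                             threshold = 0.5))
metrics_from <- function(cm, probabilities = NULL, labels = NULL) {
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  precision <- safe_div(cm$tp, cm$tp + cm$fp)
  recall <- safe_div(cm$tp, cm$tp + cm$fn)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  tibble::tibble(
    tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn, n = n,
    accuracy = safe_div(cm$tp + cm$tn, n),
    precision = precision, recall = recall,
    specificity = safe_div(cm$tn, cm$tn + cm$fp),
    f1 = f1,
    roc_auc = if (is.null(probabilities)) NA_real_ else roc_auc(probabilities, labels),
    pr_auc = if (is.null(probabilities)) NA_real_ else pr_auc(probabilities, labels),
    threshold = cm$threshold)
}

#' Reliability (calibration) curve
#'
#' Bins predictions into `n_bins` equal-width probability bins partitioning
#' \[0, 1\] and reports, per non-empty bin, the mean predicted probability
#' and the observed event fraction.
#'
#' @inheritParams roc_auc
#' @param n_bins Number of bins (default 10, minimum 2).
#' @return A `calibration_curve` tibble: `bin`, `bin_lower`, `bin_upper`,
#'   `mean_predicted`, `observed_fraction`, `n` (empty bins omitted).
#' @export
calibration_curve <- function(probabilities, labels, n_bins = 10) {
  if (n_bins < 2) stop("`n_bins` must be at least 2.", call. = FALSE)
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(findInterval(probabilities, edges, rightmost.closed = TRUE),
              n_bins)
  out <- tibble::tibble(bin = bin, p = probabilities, y = labels) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_predicted = mean(.data$p),
                     observed_fraction = mean(.data$y),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(bin_lower = edges[.data$bin], bin_upper = edges[.data$bin + 1],
                  .after = "bin")
  class(out) <- c("calibration_curve", class(out))
  out
}

#' @export
autoplot.calibration_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mean_predicted,
                                       y = .data$observed_fraction)) +
    ggplot2::geom_abline(linetype = "dashed", color = "grey60") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Mean predicted probability", y = "Observed fraction",
                  title = "Calibration curve") +
    ggplot2::theme_minimal()
}

#' Decision-curve analysis
#'
#' Net benefit of acting on the model at each threshold probability `p_t`:
#' `TP/n - (FP/n) * p_t / (1 - p_t)`, with the confusion counts taken at
#' threshold `p_t`, alongside the treat-all and treat-none reference
#' strategies (treat-none is identically 0; treat-all crosses 0 at
#' `p_t` = prevalence).
#'
#' @inheritParams roc_auc
#' @param thresholds Threshold-probability grid in (0, 1).
#' @return A `decision_curve` tibble: `threshold`, `net_benefit`,
#'   `treat_all`, `treat_none`.
#' @export
decision_curve <- function(probabilities, labels,
                           thresholds = seq(0.01, 0.60, by = 0.01)) {
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop("`thresholds` must lie strictly inside (0, 1).", call. = FALSE)
  }
  n <- length(labels)
  prev <- mean(labels == 1)
  rows <- purrr::map(thresholds, function(pt) {
    cm <- confusion_at(probabilities, labels, pt)
    w <- pt / (1 - pt)
    tibble::tibble(threshold = pt,
                   net_benefit = cm$tp / n - (cm$fp / n) * w,
                   treat_all = prev - (1 - prev) * w,
                   treat_none = 0)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("decision_curve", class(out))
  out
}

#' @export
autoplot.decision_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("net_benefit", "treat_all", "treat_none"),
                              names_to = "strategy", values_to = "nb")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$nb,
                                     color = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Threshold probability", y = "Net benefit",
                  title = "Decision curve analysis") +
    ggplot2::theme_minimal()
}

#' Metric sweep over decision thresholds
#'
#' Applies [confusion_at()] + [metrics_from()] at every grid point. Recall is
#' non-increasing and specificity non-decreasing in the threshold.
#'
#' @inheritParams roc_auc
#' @param grid Threshold grid in \[0, 1\].
#' @return Tibble with one metrics row per threshold.
#' @export
threshold_sweep <- function(probabilities, labels,
                            grid = seq(0.05, 0.95, by = 0.05)) {
  if (any(grid < 0 | grid > 1)) {
    stop("`grid` must lie within [0, 1].", call. = FALSE)
  }
  purrr::map(grid, function(t) {
    metrics_from(confusion_at(probabilities, labels, t), probabilities, labels)
  }) |> dplyr::bind_rows()
}

#' Evaluate a set of fitted models on a partition
#'
#' @param models Named list of `clin_model` / `tuned_model` objects.
#' @param data Evaluation tibble with the outcome column.
#' @param threshold Operating threshold for point metrics (default 0.5).
#' @param outcome Outcome column name.
#' @return Tibble with one metrics row per model (`model` column first).
#' @export
evaluate_models <- function(models, data, threshold = 0.5,
                            outcome = "rupture") {
  y <- as.integer(data[[outcome]])
  purrr::imap(models, function(m, nm) {
    if (inherits(m, "tuned_model")) m <- m$model
    p <- predict_prob(m, data)
    dplyr::bind_cols(tibble::tibble(model = nm),
                     metrics_from(confusion_at(p, y, threshold), p, y))
  }) |> dplyr::bind_rows()
}
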