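#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney pair statistic with midrank tie handling:
#' the probability that a randomly chosen positive receives a higher score
#' than a randomly chosen negative, counting ties as 1/2. A constant
#' predictor therefore scores exactly 0.5.
#'
#' @param scores Numeric vector of predicted scores or probabilities.
#' @param labels Binary vector (0/1 or logical) of true states.
#' @return A single number in `[0, 1]`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)) # 1
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_binary_labels(labels, scores)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC is undefined when only one class is present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Precision, recall and F-measure of binarised predictions
#'
#' F is the harmonic mean of precision and recall. Degenerate cases use the
#' conservative conventions: precision is 0 when nothing is predicted
#' positive, and F is 0 when precision + recall is 0.
#'
#' @param pred_states Binary vector of predicted states.
#' @param labels Binary vector of true states.
#' @return A one-row tibble with columns `precision`, `recall`, `f_measure`,
#'   `tp`, `fp`, `tn`, `fn`.
#' @examples
#' f_measure(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
f_measure <- function(pred_states, labels) {
  labels <- check_binary_labels(labels, pred_states)
  pred_states <- check_binary_labels(pred_states, labels)
  tp <- sum(pred_states == 1 & labels == 1)
  fp <- sum(pred_states == 1 & labels == 0)
  tn <- sum(pred_states == 0 & labels == 0)
  fn <- sum(pred_states == 0 & labels == 1)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  tibble::tibble(precision = precision, recall = recall, f_measure = f,
                 tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings, computed from the
#' contingency table of co-assignment pair counts. Symmetric in its
#' arguments and invariant to label renaming; 1 for identical partitions,
#' about 0 for independent ones.
#'
#' @param labels_a,labels_b Vectors of cluster labels (any atomic type) of
#'   equal length `n >= 2`.
#' @return A single number in `[-1, 1]`.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)) # -0.5
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  n <- length(labels_a)
  if (n < 2) stop("need at least two observations", call. = FALSE)
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) {
    # both partitions trivial (all singletons or a single block): perfect
    # agreement by convention
    return(1)
  }
  (sum_ij - expected) / (maximum - expected)
}

#' Precision-recall curve
#'
#' One point per distinct score threshold, thresholds descending, so recall
#' is non-decreasing along the curve.
#'
#' @inheritParams roc_auc
#' @return A tibble with columns `threshold`, `recall`, `precision`.
#' @export
precision_recall_curve <- function(scores, labels) {
  labels <- check_binary_labels(labels, scores)
  if (length(unique(labels)) < 2) {
    stop("precision-recall curve is undefined when only one class is present",
         call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # keep the last index of each run of tied scores
  keep <- c(diff(s) != 0, TRUE)
  tibble::tibble(
    threshold = s[keep],
    recall = tp[keep] / sum(y),
    precision = tp[keep] / (tp[keep] + fp[keep])
  )
}

#' Summarise imputation and clustering performance
#'
#' Convenience wrapper computing the full metrics panel from a prediction
#' table as returned by [impute_dataset()].
#'
#' @param predictions A tibble with columns `prob`, `pred_state` and
#'   `true_state`.
#' @param threshold Binarisation threshold applied to `prob` when
#'   `pred_state` is absent.
#' @return A one-row tibble with `auc`, `precision`, `recall`, `f_measure`
#'   and the confusion counts.
#' @export
evaluate_imputation <- function(predictions, threshold = 0.5) {
  stopifnot(all(c("prob", "true_state") %in% names(predictions)))
  pred_state <- predictions$pred_state %||%
    as.integer(predictions$prob > threshold)
  fm <- f_measure(pred_state, predictions$true_state)
  dplyr::bind_cols(
    tibble::tibble(auc = roc_auc(predictions$prob, predictions$true_state)),
    fm
  )
}

check_binary_labels <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stop("`scores` and `labels` must have equal length", call. = FALSE)
  }
  if (length(labels) == 0) stop("empty input", call. = FALSE)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be binary (0/1)", call. = FALSE)
  }
  labels
}
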