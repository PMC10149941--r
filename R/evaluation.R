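#' Macro-averaged precision, recall, F1 and accuracy
#'
#' Per-class precision, recall and F1 are computed with the 0/0 -> 0
#' convention (relevant for degenerate folds) and macro-averaged as
#' unweighted means over the class set; accuracy is the fraction of
#' correct predictions.
#'
#' @param y_true,y_pred Equal-length binary label vectors (0/1).
#' @param levels Class set to average over (default both binary classes).
#' @return A one-row tibble: `macro_precision`, `macro_recall`,
#'   `macro_f1`, `accuracy`.
#' @export
#' @examples
#' macro_metrics(c(1, 1, 0, 0), c(1, 1, 1, 1))  # macro F1 = 1/3
macro_metrics <- function(y_true, y_pred, levels = c(0L, 1L)) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred lengths differ", call. = FALSE)
  }
  if (length(y_true) == 0) stop("empty input", call. = FALSE)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  per_class <- vapply(levels, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    p <- safe_div(tp, tp + fp)
    r <- safe_div(tp, tp + fn)
    f1 <- safe_div(2 * p * r, p + r)
    c(p, r, f1)
  }, numeric(3))
  tibble::tibble(
    macro_precision = mean(per_class[1, ]),
    macro_recall = mean(per_class[2, ]),
    macro_f1 = mean(per_class[3, ]),
    accuracy = mean(y_true == y_pred)
  )
}

#' Macro-averaged ROC AUC for a binary task
#'
#' Computed by the rank (Mann-Whitney) formulation with ties credited
#' one half. For a binary task the macro average over the two classes
#' equals the positive-class AUC, because the AUC of the complementary
#' class under complementary scores is identical. Invariant under any
#' strictly monotone transform of the scores.
#'
#' @param y_true Binary labels (0/1); both classes must be present.
#' @param prob_positive Scores for the positive class.
#' @return AUC in `[0, 1]`.
#' @export
macro_auc <- function(y_true, prob_positive) {
  stopifnot(length(y_true) == length(prob_positive))
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  r <- rank(prob_positive, ties.method = "average")
  (sum(r[y_true == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' A 4x4 expert-vs-crowdsource risk confusion matrix
#'
#' Rows are expert annotations, columns crowdsourced annotations, both
#' ordered none / low / moderate / severe.
#'
#' @param counts 4x4 matrix (or 16 values, filled by row) of nonnegative
#'   integer counts.
#' @return A `risk_confusion_matrix` (a dimension-named matrix).
#' @export
risk_confusion_matrix <- function(counts) {
  if (is.matrix(counts)) {
    stopifnot(all(dim(counts) == c(4, 4)))
    m <- matrix(as.numeric(counts), 4, 4)
  } else {
    stopifnot(length(counts) == 16)
    m <- matrix(as.numeric(counts), 4, 4, byrow = TRUE)
  }
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  lv <- c("none", "low", "moderate", "severe")
  dimnames(m) <- list(expert = lv, crowdsource = lv)
  structure(m, class = c("risk_confusion_matrix", "matrix"))
}

#' Positive-class F1 agreement between annotator groups
#'
#' Collapses both axes of a 4x4 risk confusion matrix to binary through a
#' task's positive set, treats the expert axis as the reference and the
#' crowdsourced axis as the prediction, and returns the positive-class
#' F1 score `2TP / (2TP + FP + FN)`. The value is invariant under
#' transposing the matrix (F1 is symmetric in FP and FN).
#'
#' @param cm A [risk_confusion_matrix()].
#' @param task A [task_spec()] (`"flagged"` or `"urgent"`) or task name.
#' @return Positive-class F1 in `[0, 1]`.
#' @export
agreement_f1 <- function(cm, task) {
  if (is.character(task)) task <- task_spec(task)
  if (sum(cm) == 0) stop("all-zero confusion matrix", call. = FALSE)
  lv <- rownames(cm)
  pos <- lv %in% task$positive_set
  tp <- sum(cm[pos, pos])
  fn <- sum(cm[pos, !pos])
  fp <- sum(cm[!pos, pos])
  2 * tp / (2 * tp + fp + fn)
}

#' Majority-class baseline accuracy
#'
#' The accuracy achieved by always predicting the most frequent class.
#'
#' @param labels Label vector.
#' @return `max(class frequency) / n`.
#' @export
majority_baseline_accuracy <- function(labels) {
  if (length(labels) == 0) stop("empty labels", call. = FALSE)
  max(table(labels)) / length(labels)
}

#' Full metrics report for one task
#'
#' @param y_true Binary labels.
#' @param y_pred Predicted binary labels.
#' @param prob_positive Predicted positive-class probabilities (for AUC);
#'   optional.
#' @param task Label for the `task` column.
#' @return One-row tibble: `task`, `macro_precision`, `macro_recall`,
#'   `macro_f1`, `accuracy`, `macro_auc`.
#' @export
metrics_report <- function(y_true, y_pred, prob_positive = NULL,
                           task = "task") {
  mm <- macro_metrics(y_true, y_pred)
  auc <- if (is.null(prob_positive)) NA_real_
         else macro_auc(y_true, prob_positive)
  dplyr::bind_cols(tibble::tibble(task = task), mm,
                   tibble::tibble(macro_auc = auc))
}
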