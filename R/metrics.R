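#' One-vs-rest confusion counts
#'
#' For each class c: `tp_c` (predicted c, truly c), `fp_c` (predicted c,
#' truly other), `fn_c` (predicted other, truly c) and `tn_c` (neither);
#' the four counts partition the N predictions for every class.
#'
#' @param truth,pred Label vectors of equal length.
#' @param levels Class levels (default: union of both, sorted).
#' @return An object of class `confusion_stats`: the C x C confusion matrix
#'   (rows = truth, cols = predicted) plus per-class `tp`, `fp`, `fn`, `tn`,
#'   supports `n_c`, and `N`.
#' @export
confusion_stats <- function(truth, pred, levels = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred) || length(truth) == 0L)
    stop("confusion_stats: truth and pred must be non-empty and equal length")
  if (is.null(levels)) levels <- sort(unique(c(truth, pred)))
  tf <- factor(truth, levels = levels)
  pf <- factor(pred, levels = levels)
  if (anyNA(tf) || anyNA(pf)) stop("confusion_stats: label outside 'levels'")
  cm <- table(truth = tf, predicted = pf)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  N <- length(truth)
  structure(list(matrix = cm, tp = as.numeric(tp), fp = as.numeric(fp),
                 fn = as.numeric(fn),
                 tn = as.numeric(N - tp - fp - fn),
                 n_c = as.numeric(rowSums(cm)), N = N, levels = levels),
            class = "confusion_stats")
}

#' Multi-class identification metrics
#'
#' Computes the evaluation suite from label/prediction vectors:
#' per-class precision `tp_c / (tp_c + fp_c)` and recall
#' `tp_c / (tp_c + fn_c)`; overall precision (OP) and recall (OR) as their
#' macro means; overall accuracy (OA) as the proportion of correctly
#' predicted labels; and the support-weighted F1 score
#' `sum_c 2 (n_c / N) * P_c R_c / (P_c + R_c)`. A class with zero predicted
#' (or actual) positives contributes 0 to the affected metric, with a
#' warning, rather than dividing by zero.
#'
#' @inheritParams confusion_stats
#' @return An object of class `eval_report` with per-class and overall
#'   metrics and the underlying [confusion_stats()].
#' @examples
#' eval_metrics(c("a", "a", "b", "b"), c("a", "b", "b", "b"))
#' @export
eval_metrics <- function(truth, pred, levels = NULL) {
  cs <- confusion_stats(truth, pred, levels)
  safe_div <- function(num, den, what) {
    bad <- den == 0
    if (any(bad))
      warning(sprintf("class(es) %s: no %s; contributing 0",
                      paste(cs$levels[bad], collapse = ", "), what))
    ifelse(den == 0, 0, num / den)
  }
  precision <- safe_div(cs$tp, cs$tp + cs$fp, "predicted positives")
  recall <- safe_div(cs$tp, cs$tp + cs$fn, "actual positives")
  pr_sum <- precision + recall
  f1_terms <- ifelse(pr_sum == 0, 0,
                     2 * (cs$n_c / cs$N) * precision * recall / pr_sum)
  structure(list(per_class_precision = stats::setNames(precision, cs$levels),
                 per_class_recall = stats::setNames(recall, cs$levels),
                 overall_precision = mean(precision),
                 overall_recall = mean(recall),
                 overall_accuracy = sum(cs$tp) / cs$N,
                 f1_score = sum(f1_terms),
                 confusion = cs),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("ECG identification evaluation\n")
  cat(sprintf("  %d classes, %d windows\n", length(x$confusion$levels),
              x$confusion$N))
  cat(sprintf("  Overall accuracy : %6.2f%%\n", 100 * x$overall_accuracy))
  cat(sprintf("  Overall precision: %6.2f%%\n", 100 * x$overall_precision))
  cat(sprintf("  Overall recall   : %6.2f%%\n", 100 * x$overall_recall))
  cat(sprintf("  F1 score         : %.4f\n", x$f1_score))
  invisible(x)
}

#' Summary table row in the reference layout
#'
#' Formats one evaluation as a one-row data frame in the layout of the
#' reference performance tables (cell type, input sequence length, number of
#' hidden layers, OA, OP, OR, F1).
#'
#' @param report An [eval_metrics()] report.
#' @param model Optional fitted `drnn` supplying the architecture columns.
#' @param input_len Label for the input sequence length column.
#' @return A one-row `data.frame`.
#' @export
report_row <- function(report, model = NULL, input_len = NA) {
  data.frame(
    cell = if (is.null(model)) NA_character_
           else if (model$arch$bidirectional) "BiLSTM" else "LSTM",
    input_length = input_len,
    hidden_layers = if (is.null(model)) NA_integer_ else model$arch$num_layers,
    OA = 100 * report$overall_accuracy,
    OP = 100 * report$overall_precision,
    OR = 100 * report$overall_recall,
    F1 = report$f1_score)
}

#' Evaluate a fitted model on held-out windows
#'
#' Predicts every window of the test set and scores the predictions with
#' [eval_metrics()] against the model's full class-level set.
#'
#' @param model A fitted `drnn`.
#' @param test_set A non-empty [segment_set()].
#' @return An `eval_report`.
#' @export
evaluate <- function(model, test_set) {
  stopifnot(inherits(test_set, "segment_set"))
  if (nrow(test_set$windows) == 0L) stop("evaluate: empty test set")
  pred <- predict(model, test_set, type = "class")
  eval_metrics(test_set$labels, pred, levels = model$class_levels)
}
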