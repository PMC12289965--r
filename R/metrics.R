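#' Confusion matrix from predicted and true labels
#'
#' @param predicted,truth integer vectors of 0/1 labels, same length.
#' @return a `confusion_matrix`: list with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_matrix <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth), length(truth) > 0,
            all(predicted %in% 0:1), all(truth %in% 0:1))
  structure(list(tp = sum(predicted == 1 & truth == 1),
                 fp = sum(predicted == 1 & truth == 0),
                 fn = sum(predicted == 0 & truth == 1),
                 tn = sum(predicted == 0 & truth == 0)),
            class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' Precision `tp/(tp+fp)`, recall `tp/(tp+fn)`, their harmonic mean F1, and
#' accuracy. A zero denominator yields `NA` ("flagged undefined") for that
#' metric; F1 is undefined whenever precision or recall is.
#'
#' @param cm a [confusion_matrix()] (or a list with `tp`, `fp`, `fn`, `tn`).
#' @return a `metrics` list: `precision`, `recall`, `f1`, `accuracy`.
#' @export
#' @examples
#' compute_metrics(list(tp = 9, fn = 2, fp = 0, tn = 11))
compute_metrics <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  total <- tp + fp + fn + tn
  stopifnot(total > 0, tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  structure(list(precision = precision, recall = recall, f1 = f1,
                 accuracy = (tp + tn) / total),
            class = "metrics")
}

#' @export
print.metrics <- function(x, ...) {
  cat(sprintf("precision %.3f  recall %.3f  F1 %.3f  accuracy %.3f\n",
              x$precision, x$recall, x$f1, x$accuracy))
  invisible(x)
}

#' Evaluate a trained model on a test set
#'
#' @param model a [train_classifier()] result (or any object with a
#'   [predict_example()] method contract).
#' @param test_set list of `labeled_example`s (nonempty).
#' @return list with `confusion` ([confusion_matrix()]), `metrics`
#'   ([compute_metrics()]) and the per-example `scores`.
#' @export
evaluate <- function(model, test_set) {
  stopifnot(length(test_set) > 0)
  truth <- vapply(test_set, `[[`, integer(1), "label")
  preds <- vapply(test_set, function(e) predict_example(model, e$tensor),
                  numeric(2))
  cm <- confusion_matrix(as.integer(preds["label", ]), truth)
  list(confusion = cm, metrics = compute_metrics(cm),
       scores = preds["score", ])
}
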