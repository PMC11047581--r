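#' Per-class precision/recall/F1 report
#'
#' Computes one-vs-rest true positives, false positives, and false
#' negatives per class, with precision `p = TP/(TP+FP)`, recall
#' `r = TP/(TP+FN)` (0/0 defined as 0), and
#' `F1 = 2pr/(p+r) = 2TP/(2TP+FP+FN)`, plus macro averages.
#'
#' @param y_true,y_pred Equal-length integer label vectors with values in
#'   `[0, n_classes)`.
#' @param n_classes Number of classes.
#' @return A `class_metrics` object: data frame `per_class` with columns
#'   `class`, `tp`, `fp`, `fn`, `precision`, `recall`, `f1`, and scalars
#'   `macro_precision`, `macro_recall`, `macro_f1`, `accuracy`.
#' @export
classification_report <- function(y_true, y_pred, n_classes) {
  if (length(y_true) != length(y_pred)) stopf("label vectors differ in length")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (any(c(y_true, y_pred) < 0L) || any(c(y_true, y_pred) >= n_classes)) {
    stopf("labels outside [0, %d)", n_classes)
  }
  tp <- fp <- fn <- integer(n_classes)
  for (k in seq_len(n_classes) - 1L) {
    tp[k + 1L] <- sum(y_true == k & y_pred == k)
    fp[k + 1L] <- sum(y_true != k & y_pred == k)
    fn[k + 1L] <- sum(y_true == k & y_pred != k)
  }
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  p <- safe_div(tp, tp + fp)
  r <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * tp, 2 * tp + fp + fn)
  per <- data.frame(class = seq_len(n_classes) - 1L, tp = tp, fp = fp,
                    fn = fn, precision = p, recall = r, f1 = f1)
  structure(list(per_class = per,
                 macro_precision = mean(p), macro_recall = mean(r),
                 macro_f1 = mean(f1),
                 accuracy = mean(y_true == y_pred)),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat("<class_metrics>\n")
  print(x$per_class, row.names = FALSE, digits = 3)
  cat(sprintf("  macro F1 %.3f  accuracy %.3f\n", x$macro_f1, x$accuracy))
  invisible(x)
}
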