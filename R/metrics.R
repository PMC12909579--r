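#' Classification metrics for multi-stage grading
#'
#' Per-class precision/recall/F1 from one-vs-rest confusion-matrix marginals,
#' overall accuracy and error rate (trace over total), binary and multiclass
#' Matthews correlation (the K-class R_K statistic over confusion marginals),
#' macro and support-weighted aggregation, and reconstruction of confusion
#' marginals from published per-class tables. Any rate with a zero denominator
#' is reported as 0.
#'
#' @name metrics
NULL

#' Confusion matrix from label sequences
#'
#' @param y_true,y_pred Equal-length vectors of class labels.
#' @param labels Ordered vector of all class labels; must cover every observed
#'   value. Defaults to the sorted union of observed labels.
#' @return Integer K x K matrix, rows = true class, columns = predicted class,
#'   with `dimnames` set to the labels.
#' @export
confusion_matrix <- function(y_true, y_pred, labels = NULL) {
  if (length(y_true) != length(y_pred))
    stop("confusion_matrix: y_true and y_pred differ in length")
  if (is.null(labels)) labels <- sort(unique(c(y_true, y_pred)))
  labels <- as.character(labels)
  ti <- match(as.character(y_true), labels)
  pi <- match(as.character(y_pred), labels)
  if (anyNA(ti) || anyNA(pi))
    stop("confusion_matrix: observed label not covered by `labels`")
  K <- length(labels)
  cm <- matrix(0L, K, K, dimnames = list(true = labels, predicted = labels))
  if (length(ti))
    for (t in seq_along(ti)) cm[ti[t], pi[t]] <- cm[ti[t], pi[t]] + 1L
  cm
}

ovr_counts <- function(cm) {
  total <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  list(tp = tp, fp = fp, fn = fn, tn = tn, total = total)
}

safe_div <- function(num, den) ifelse(den > 0, num / den, 0)

#' Per-class precision, recall and F1
#'
#' One-vs-rest marginals per class: precision = TP/(TP+FP),
#' recall = TP/(TP+FN), F1 = 2PR/(P+R); zero denominators yield 0.
#'
#' @param cm Confusion matrix as from [confusion_matrix()].
#' @return Data frame with one row per class: `class`, `precision`, `recall`,
#'   `f1`, `support`.
#' @export
per_class_metrics <- function(cm) {
  oc <- ovr_counts(cm)
  precision <- safe_div(oc$tp, oc$tp + oc$fp)
  recall <- safe_div(oc$tp, oc$tp + oc$fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  data.frame(class = rownames(cm), precision = unname(precision),
             recall = unname(recall), f1 = unname(f1),
             support = unname(rowSums(cm)), row.names = NULL)
}

#' Accuracy and error rate
#'
#' @param cm Confusion matrix with a positive total count.
#' @return `list(accuracy, error_rate)` with
#'   `accuracy = sum(diag(cm)) / sum(cm)` and `error_rate = 1 - accuracy`.
#' @export
accuracy_error <- function(cm) {
  total <- sum(cm)
  if (total <= 0) stop("accuracy_error: empty confusion matrix")
  acc <- sum(diag(cm)) / total
  list(accuracy = acc, error_rate = 1 - acc)
}

#' Binary Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; returns 0 whenever
#' a factor under the root is 0.
#'
#' @param tp,tn,fp,fn Non-negative counts.
#' @return Value in `[-1, 1]`.
#' @export
mcc_binary <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  den2 <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
  if (den2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den2)
}

#' Multiclass Matthews correlation (R_K statistic)
#'
#' With `c` the diagonal sum, `s` the total, `t_k` the row sums and `p_k` the
#' column sums of the confusion matrix:
#' `(c*s - sum(p_k t_k)) / sqrt((s^2 - sum(p_k^2)) (s^2 - sum(t_k^2)))`.
#' A zero denominator yields 0. Coincides with [mcc_binary()] for K = 2.
#'
#' @param cm Confusion matrix.
#' @return Value in `[-1, 1]`.
#' @export
mcc_multiclass <- function(cm) {
  s <- sum(cm)
  if (s <= 0) stop("mcc_multiclass: empty confusion matrix")
  cc <- sum(diag(cm))
  t_k <- rowSums(cm); p_k <- colSums(cm)
  num <- cc * s - sum(p_k * t_k)
  den2 <- (s^2 - sum(p_k^2)) * (s^2 - sum(t_k^2))
  if (den2 <= 0) return(0)
  num / sqrt(den2)
}

#' Macro and support-weighted averages of per-class metrics
#'
#' @param values Numeric vector of a per-class metric.
#' @param supports Positive per-class sample counts.
#' @return `list(macro, weighted)`: unweighted and support-weighted means.
#' @export
aggregate_metrics <- function(values, supports) {
  stopifnot(length(values) == length(supports), all(supports > 0))
  list(macro = mean(values),
       weighted = sum(values * supports) / sum(supports))
}

#' Reconstruct confusion-matrix marginals from a published per-class table
#'
#' Published per-class tables print precision, recall and supports but not the
#' confusion matrix. Since recall_k = diagonal_k / support_k and
#' precision_k = diagonal_k / column_k with integer counts,
#' `diagonal_k = round(recall_k * support_k)` and
#' `column_k = round(diagonal_k / precision_k)` recover the diagonal and the
#' predicted-class totals, which is all the K-class MCC needs. Conservation
#' (`sum(column) == sum(support)`) is checked to within K counts.
#'
#' @param precision,recall Per-class values as printed.
#' @param supports Per-class true-class counts.
#' @return `list(diagonal, columns, supports, conserved)`.
#' @export
reconstruct_marginals <- function(precision, recall, supports) {
  K <- length(supports)
  stopifnot(length(precision) == K, length(recall) == K)
  if (any(recall > 0 & precision <= 0))
    stop("reconstruct_marginals: positive recall requires positive precision")
  diagonal <- round(recall * supports)
  columns <- ifelse(precision > 0, round(diagonal / precision), 0)
  drift <- abs(sum(columns) - sum(supports))
  if (drift > K)
    stop("reconstruct_marginals: column totals miss sample conservation by ",
         drift, " (> K = ", K, "); inputs inconsistent")
  list(diagonal = as.numeric(diagonal), columns = as.numeric(columns),
       supports = as.numeric(supports), conserved = drift == 0)
}

#' Multiclass MCC from reconstructed marginals
#'
#' The R_K statistic only involves the diagonal, the row totals and the column
#' totals, so it can be evaluated directly from [reconstruct_marginals()]
#' output without the full matrix.
#'
#' @param marginals Output of [reconstruct_marginals()], or any list with
#'   `diagonal`, `columns`, `supports`.
#' @return Value in `[-1, 1]`.
#' @export
mcc_from_marginals <- function(marginals) {
  s <- sum(marginals$supports)
  cc <- sum(marginals$diagonal)
  t_k <- marginals$supports; p_k <- marginals$columns
  den2 <- (s^2 - sum(p_k^2)) * (s^2 - sum(t_k^2))
  if (den2 <= 0) return(0)
  (cc * s - sum(p_k * t_k)) / sqrt(den2)
}

#' Full classification report
#'
#' Assembles per-class metrics, accuracy, error rate, multiclass MCC and
#' macro/weighted aggregates, mirroring the layout of published per-class
#' result tables.
#'
#' @inheritParams confusion_matrix
#' @return A `classification_report`: `per_class` (data frame), `accuracy`,
#'   `error_rate`, `mcc`, `macro_avg` and `weighted_avg` (precision, recall,
#'   f1 each), `confusion` (the matrix).
#' @export
classification_report <- function(y_true, y_pred, labels = NULL) {
  cm <- confusion_matrix(y_true, y_pred, labels)
  report_from_cm(cm)
}

#' @rdname classification_report
#' @param cm A confusion matrix.
#' @export
report_from_cm <- function(cm) {
  pc <- per_class_metrics(cm)
  ae <- accuracy_error(cm)
  agg <- lapply(c(precision = "precision", recall = "recall", f1 = "f1"),
                function(col) aggregate_metrics(pc[[col]], pc$support))
  structure(list(
    per_class = pc,
    accuracy = ae$accuracy,
    error_rate = ae$error_rate,
    mcc = mcc_multiclass(cm),
    macro_avg = vapply(agg, `[[`, numeric(1), "macro"),
    weighted_avg = vapply(agg, `[[`, numeric(1), "weighted"),
    confusion = cm), class = "classification_report")
}

#' @export
print.classification_report <- function(x, digits = 6, ...) {
  cat("classification report\n")
  print(cbind(format(x$per_class[1], justify = "left"),
              round(x$per_class[-1], digits)), row.names = FALSE)
  cat(sprintf("accuracy %.6f  error_rate %.6f  mcc %.6f\n",
              x$accuracy, x$error_rate, x$mcc))
  cat(sprintf("macro    P %.6f  R %.6f  F1 %.6f\n",
              x$macro_avg["precision"], x$macro_avg["recall"], x$macro_avg["f1"]))
  cat(sprintf("weighted P %.6f  R %.6f  F1 %.6f\n",
              x$weighted_avg["precision"], x$weighted_avg["recall"],
              x$weighted_avg["f1"]))
  invisible(x)
}

#' Serialize a classification report to JSON
#'
#' @param report A `classification_report`.
#' @param path Output file.
#' @return `path` invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "classification_report"))
  obj <- list(per_class = report$per_class,
              accuracy = report$accuracy,
              error_rate = report$error_rate,
              mcc = report$mcc,
              macro_avg = as.list(report$macro_avg),
              weighted_avg = as.list(report$weighted_avg))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
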