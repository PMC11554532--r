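# Confusion-matrix metric suite: accuracy, macro precision / recall /
# F1 / one-vs-rest AUC, FNR (complement of macro recall), generalized
# (Gorodkin) multiclass Matthews correlation, and Cohen's kappa.
# Percentages are reported on the 0-100 scale; MCC, kappa and AUC on
# their native scales.

#' Confusion matrix
#'
#' @param truth,pred integer class indices (1-based).
#' @param k number of classes.
#' @return `k x k` count matrix, rows = truth, columns = predicted.
#' @export
confusion_matrix <- function(truth, pred, k) {
  cm <- matrix(0L, k, k)
  for (i in seq_along(truth))
    cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1L
  cm
}

# Generalized (Gorodkin) multiclass Matthews correlation from counts.
mcc_from_cm <- function(cm) {
  s <- sum(cm); c0 <- sum(diag(cm))
  t_k <- rowSums(cm); p_k <- colSums(cm)
  num <- c0 * s - sum(p_k * t_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) return(0)
  num / den
}

# Cohen's kappa with marginal expected agreement.
kappa_from_cm <- function(cm) {
  s <- sum(cm)
  po <- sum(diag(cm)) / s
  pe <- sum(rowSums(cm) * colSums(cm)) / s^2
  if (abs(1 - pe) < 1e-12) return(0)
  (po - pe) / (1 - pe)
}

# Macro one-vs-rest AUC from a class-probability matrix.
auc_macro_ovr <- function(truth, probs) {
  k <- ncol(probs)
  aucs <- numeric(0)
  for (cl in seq_len(k)) {
    y <- truth == cl
    if (!any(y) || all(y)) next
    a <- suppressMessages(pROC::auc(
      response = factor(y, levels = c(FALSE, TRUE)),
      predictor = probs[, cl], direction = "<", quiet = TRUE))
    aucs <- c(aucs, as.numeric(a))
  }
  if (!length(aucs)) return(NA_real_)
  mean(aucs)
}

#' Metrics report from predictions
#'
#' Computes the full metric suite from true labels and a class-score
#' matrix (predicted class = column argmax). A class that is never
#' predicted contributes precision 0 (logged as a message).
#'
#' @param truth integer true labels (1-based).
#' @param probs numeric `n x k` class-score matrix.
#' @param class_names optional class names.
#' @return an object of class `metrics_report`: `accuracy`, `precision`,
#'   `recall`, `f1`, `fnr` (all percentages), `auc`, `mcc`, `kappa`, and
#'   the `confusion` count matrix.
#' @export
metrics_report <- function(truth, probs, class_names = NULL) {
  k <- ncol(probs)
  pred <- max.col(probs, ties.method = "first")
  cm <- confusion_matrix(truth, pred, k)
  if (!is.null(class_names)) dimnames(cm) <- list(class_names, class_names)
  tp <- diag(cm); rows <- rowSums(cm); cols <- colSums(cm)
  if (any(cols == 0 & rows > 0))
    message(sprintf("class(es) %s never predicted; precision taken as 0",
                    paste(which(cols == 0 & rows > 0), collapse = ", ")))
  prec <- ifelse(cols == 0, 0, tp / cols)
  rec <- ifelse(rows == 0, 0, tp / rows)
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  present <- rows > 0  # macro averages over classes present in truth
  macro_rec <- 100 * mean(rec[present])
  structure(list(
    accuracy = 100 * sum(tp) / sum(cm),
    precision = 100 * mean(prec[present]),
    recall = macro_rec,
    f1 = 100 * mean(f1[present]),
    auc = auc_macro_ovr(truth, probs),
    fnr = 100 - macro_rec,
    mcc = mcc_from_cm(cm),
    kappa = kappa_from_cm(cm),
    confusion = cm), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report> accuracy %.2f%%, precision %.2f%%, ",
                     "recall %.2f%%, F1 %.2f%%, AUC %.3f, FNR %.2f%%, ",
                     "MCC %.4f, kappa %.4f\n"),
              x$accuracy, x$precision, x$recall, x$f1, x$auc, x$fnr,
              x$mcc, x$kappa))
  invisible(x)
}

#' Persist a metrics report
#'
#' @param report a `metrics_report`.
#' @param path JSON output path.
#' @param cm_csv optional CSV path for the confusion matrix.
#' @export
write_metrics_report <- function(report, path, cm_csv = NULL) {
  doc <- unclass(report)
  doc$confusion <- as.data.frame(report$confusion)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(cm_csv))
    utils::write.csv(as.data.frame(report$confusion), cm_csv)
  invisible(path)
}
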