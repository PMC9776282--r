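# Evaluation: confusion matrix and per-class one-vs-rest metrics.
#
# For class i with true-positive TP, true-negative TN, false-positive FP and
# false-negative FN counts:
#   Precision   = TP / (TP + FP)
#   Specificity = TN / (TN + FP)
#   Sensitivity = Recall = TP / (TP + FN)
#   F1          = 2 * Precision * Recall / (Precision + Recall)
#   G-mean      = sqrt(Recall * Specificity)
# A zero denominator yields 0 (the convention used for absent or never-
# predicted classes in heavily imbalanced data).

safe_div <- function(num, den) ifelse(den > 0, num / den, 0)

#' F1 score from precision and recall
#'
#' Harmonic mean `2 P R / (P + R)`; 0 when both are 0.
#' @param precision,recall per-class rates in `[0, 1]`.
#' @return F1 score.
#' @export
f1_score <- function(precision, recall) {
  safe_div(2 * precision * recall, precision + recall)
}

#' G-mean from recall and specificity
#'
#' Geometric mean `sqrt(Recall * Specificity)`.
#' @param recall,specificity per-class rates in `[0, 1]`.
#' @return G-mean.
#' @export
g_mean <- function(recall, specificity) sqrt(recall * specificity)

#' Per-class metrics from a confusion matrix
#'
#' @param confusion square matrix of counts, rows = true class, columns =
#'   predicted class (dimnames, if present, name the classes).
#' @return Object of class `fer_metrics`: list with `confusion`,
#'   `confusion_prop` (row-normalized), `accuracy` (trace / total) and
#'   `per_class` (data frame with precision, specificity, sensitivity, f1,
#'   g_mean per class).
#' @export
compute_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    stop("confusion matrix must be square, got ", nrow(confusion), " x ",
         ncol(confusion))
  if (any(confusion < 0) || any(!is.finite(confusion)))
    stop("confusion matrix must hold non-negative finite counts")
  classes <- rownames(confusion)
  if (is.null(classes)) classes <- paste0("class", seq_len(nrow(confusion)))
  total <- sum(confusion)
  tp <- diag(confusion)
  fn <- rowSums(confusion) - tp
  fp <- colSums(confusion) - tp
  tn <- total - tp - fn - fp
  precision <- safe_div(tp, tp + fp)
  specificity <- safe_div(tn, tn + fp)
  sensitivity <- safe_div(tp, tp + fn)
  per_class <- data.frame(class = classes, tp = tp, tn = tn, fp = fp,
                          fn = fn, precision = precision,
                          specificity = specificity,
                          sensitivity = sensitivity,
                          f1 = f1_score(precision, sensitivity),
                          g_mean = g_mean(sensitivity, specificity),
                          row.names = NULL)
  rs <- rowSums(confusion)
  prop <- sweep(confusion, 1, ifelse(rs > 0, rs, 1), "/")
  structure(list(confusion = confusion, confusion_prop = prop,
                 accuracy = if (total > 0) sum(tp) / total else 0,
                 per_class = per_class, n = total),
            class = "fer_metrics")
}

#' @export
print.fer_metrics <- function(x, digits = 3, ...) {
  cat(sprintf("accuracy: %.*f  (n = %d)\n", digits, x$accuracy, x$n))
  pc <- x$per_class
  pc[, -1] <- round(pc[, -1], digits)
  print(pc[, c("class", "precision", "specificity", "sensitivity", "f1",
               "g_mean")], row.names = FALSE)
  invisible(x)
}

#' Evaluate a trained model on labeled data
#'
#' Runs eval-mode forward passes (stored neutral baseline and normalization
#' statistics, hence batch-size independent), builds the true-by-predicted
#' confusion matrix over the model vocabulary and derives all per-class
#' metrics.
#'
#' @param model a trained `pcvt_model`.
#' @param data `list(x, y)` or manifest data frame / CSV path.
#' @param batch_size evaluation batch size (does not affect results).
#' @return A `fer_metrics` object (see [compute_metrics()]).
#' @export
evaluate_model <- function(model, data, batch_size = 64) {
  data <- as_image_data(data, model)
  B <- dim(data$x)[4]
  if (B == 0) stop("empty manifest: nothing to evaluate")
  preds <- integer(B)
  for (start in seq(1, B, by = batch_size)) {
    bidx <- start:min(start + batch_size - 1, B)
    fw <- fwd_model(model, data$x[, , , bidx, drop = FALSE], train = FALSE)
    preds[bidx] <- apply(fw$logits, 2, which.max)
  }
  k <- length(model$vocab)
  cm <- table(factor(data$y, levels = seq_len(k)),
              factor(preds, levels = seq_len(k)))
  cm <- matrix(as.integer(cm), k, k,
               dimnames = list(model$vocab, model$vocab))
  compute_metrics(cm)
}

#' Write a metrics report as JSON
#'
#' The report holds the confusion matrix both as counts and row-normalized
#' proportions, plus the per-class metrics, values at 3 decimals.
#'
#' @param metrics a `fer_metrics` object.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(metrics, path) {
  obj <- list(n = metrics$n,
              accuracy = round(metrics$accuracy, 3),
              classes = metrics$per_class$class,
              confusion_counts = unname(apply(metrics$confusion, 1, c,
                                              simplify = FALSE)),
              confusion_row_prop = unname(apply(
                round(metrics$confusion_prop, 3), 1, c, simplify = FALSE)),
              per_class = cbind(metrics$per_class["class"],
                                round(metrics$per_class[, c(
                                  "precision", "specificity", "sensitivity",
                                  "f1", "g_mean")], 3)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
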