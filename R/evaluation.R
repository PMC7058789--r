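#' Confusion matrix (predicted x true)
#'
#' Rows index the predicted class and columns the true class, in the given
#' class order, matching the layout of the diagnostic performance tables
#' (IPMN / MCN / SCA).
#'
#' @param true_labels,predicted_labels equal-length label vectors.
#' @param class_order character vector fixing the row/column order
#'   (default `c("IPMN", "MCN", "SCA")`).
#' @return Integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(true_labels, predicted_labels,
                      class_order = c("IPMN", "MCN", "SCA")) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length", call. = FALSE)
  if (!all(c(true_labels, predicted_labels) %in% class_order))
    stop("invalid label: outside the declared class order", call. = FALSE)
  cm <- table(factor(predicted_labels, levels = class_order),
              factor(true_labels, levels = class_order))
  m <- matrix(as.integer(cm), nrow = length(class_order),
              dimnames = list(predicted = class_order, true = class_order))
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' Per-class precision, recall, F1 and overall accuracy
#'
#' Precision of class c is the fraction of patients predicted c that truly
#' are c (`cm[c, c] / row_sum(c)`); recall is the fraction of true-c
#' patients predicted c (`cm[c, c] / col_sum(c)`); F1 is their harmonic
#' mean `2 P R / (P + R)`; overall accuracy is `trace / total`. A zero
#' denominator yields 0 for the affected metric, flagged in the result.
#'
#' @param cm a `confusion_matrix` (or any square count matrix, rows =
#'   predicted, columns = true).
#' @return An object of class `metrics_report`: `data.frame` `per_class`
#'   (precision, recall, f1), `overall_accuracy`, `n`, and
#'   `zero_denominator` flags.
#' @export
metrics <- function(cm) {
  cm <- unclass(as.matrix(cm))
  if (nrow(cm) != ncol(cm) || any(cm < 0) || sum(cm) == 0)
    stop("invalid argument: need a non-empty square count matrix",
         call. = FALSE)
  classes <- rownames(cm)
  if (is.null(classes)) classes <- paste0("class", seq_len(nrow(cm)))
  tp <- diag(cm)
  rs <- rowSums(cm)
  cs <- colSums(cm)
  precision <- ifelse(rs > 0, tp / rs, 0)
  recall <- ifelse(cs > 0, tp / cs, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  flagged <- rs == 0 | cs == 0 | (precision + recall) == 0
  structure(list(
    per_class = data.frame(class = classes, precision = unname(precision),
                           recall = unname(recall), f1 = unname(f1),
                           row.names = NULL, stringsAsFactors = FALSE),
    overall_accuracy = sum(tp) / sum(cm),
    n = sum(cm),
    zero_denominator = classes[flagged]),
    class = "metrics_report")
}

# half-up rounding to 4 decimals, the display convention of the report
round4 <- function(x) floor(x * 1e4 + 0.5) / 1e4

#' @export
print.metrics_report <- function(x, ...) {
  df <- x$per_class
  df$precision <- sprintf("%.4f", round4(df$precision))
  df$recall <- sprintf("%.4f", round4(df$recall))
  df$f1 <- sprintf("%.4f", round4(df$f1))
  print(df, row.names = FALSE)
  cat(sprintf("OA %.4f (n = %d)\n", round4(x$overall_accuracy), x$n))
  if (length(x$zero_denominator))
    cat("zero-denominator classes:",
        paste(x$zero_denominator, collapse = ", "), "\n")
  invisible(x)
}

#' Render training/validation metrics side by side
#'
#' One formatted table per model in the layout of the diagnostic
#' performance tables: per-class confusion counts followed by precision,
#' recall and F1 at 4 decimals, training and validation side by side, with
#' the overall accuracies in the footer row.
#'
#' @param cm_train,cm_valid `confusion_matrix` objects.
#' @return Character vector of formatted lines (also printed).
#' @export
format_metrics_table <- function(cm_train, cm_valid) {
  mt <- metrics(cm_train)
  mv <- metrics(cm_valid)
  classes <- rownames(cm_train)
  lines <- sprintf("%-6s %s  %-24s %s  %s",
                   "TP", paste(sprintf("%5s", classes), collapse = " "),
                   "Pre    Rec    F1",
                   paste(sprintf("%5s", classes), collapse = " "),
                   "Pre    Rec    F1")
  for (k in seq_along(classes)) {
    lines <- c(lines, sprintf(
      "%-6s %s  %.4f %.4f %.4f    %s  %.4f %.4f %.4f",
      classes[k],
      paste(sprintf("%5d", cm_train[k, ]), collapse = " "),
      round4(mt$per_class$precision[k]), round4(mt$per_class$recall[k]),
      round4(mt$per_class$f1[k]),
      paste(sprintf("%5d", cm_valid[k, ]), collapse = " "),
      round4(mv$per_class$precision[k]), round4(mv$per_class$recall[k]),
      round4(mv$per_class$f1[k])))
  }
  lines <- c(lines, sprintf(
    "%-6s %s  OA %.4f%s%s  OA %.4f", "Total",
    paste(sprintf("%5d", colSums(cm_train)), collapse = " "),
    round4(mt$overall_accuracy),
    strrep(" ", 12),
    paste(sprintf("%5d", colSums(cm_valid)), collapse = " "),
    round4(mv$overall_accuracy)))
  cat(lines, sep = "\n")
  invisible(lines)
}
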