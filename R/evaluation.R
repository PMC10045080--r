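# Confusion-matrix construction and the five evaluation metrics
# (sensitivity, precision, accuracy, specificity, AUC), computed per
# class under the one-vs-rest reduction and macro-averaged.

#' Confusion matrix
#'
#' `counts[i, j]` is the number of samples with true class i predicted
#' as class j; rows are true classes, in the fixed `class_names` order.
#'
#' @param true_labels,predicted_labels character vectors of equal
#'   length with values in `class_names`.
#' @param class_names ordered class vocabulary.
#' @return integer matrix with class dimnames.
#' @export
confusion <- function(true_labels, predicted_labels,
                      class_names = sort(unique(c(true_labels,
                                                  predicted_labels)))) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors differ in length", call. = FALSE)
  if (!all(true_labels %in% class_names) ||
      !all(predicted_labels %in% class_names))
    stop("labels outside the class vocabulary", call. = FALSE)
  tt <- table(factor(true_labels, levels = class_names),
              factor(predicted_labels, levels = class_names))
  cm <- matrix(as.integer(tt), nrow = length(class_names),
               dimnames = list(true = class_names, predicted = class_names))
  cm
}

ovr_counts <- function(cm, k) {
  tp <- cm[k, k]
  fn <- sum(cm[k, ]) - tp
  fp <- sum(cm[, k]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(tp = tp, fn = fn, fp = fp, tn = tn)
}

ratio_pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den

#' Per-class one-vs-rest metrics
#'
#' For each class k the confusion matrix is reduced to a binary problem
#' (TP = `cm[k, k]`, FN = rest of row k, FP = rest of column k, TN =
#' everything else) and sensitivity TP/(TP+FN), precision TP/(TP+FP),
#' accuracy (TP+TN)/total and specificity TN/(TN+FP) are reported in
#' percent. Undefined ratios (0/0) are reported as `NA`, never as 0 or
#' 100.
#'
#' @param cm a [confusion()] matrix.
#' @return data frame with one row per class.
#' @export
per_class_metrics <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  if (sum(cm) == 0L) stop("empty confusion matrix", call. = FALSE)
  classes <- rownames(cm)
  rows <- lapply(seq_len(nrow(cm)), function(k) {
    ct <- ovr_counts(cm, k)
    data.frame(class = classes[k],
               sensitivity = ratio_pct(ct["tp"], ct["tp"] + ct["fn"]),
               precision = ratio_pct(ct["tp"], ct["tp"] + ct["fp"]),
               accuracy = ratio_pct(ct["tp"] + ct["tn"], sum(ct)),
               specificity = ratio_pct(ct["tn"], ct["tn"] + ct["fp"]),
               row.names = NULL)
  })
  do.call(rbind, rows)
}

# ROC curve for one class by threshold sweep over the scores.
roc_curve <- function(scores, positive) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- positive[ord]
  npos <- sum(positive); nneg <- sum(!positive)
  # group tied thresholds so ties produce diagonal segments
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  data.frame(threshold = c(Inf, s[last]),
             tpr = c(0, tp[last] / npos),
             fpr = c(0, fp[last] / nneg))
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' One-vs-rest ROC AUC per class
#'
#' Area under the one-vs-rest ROC curve, computed by a threshold sweep
#' with trapezoidal integration (equivalent to the Mann-Whitney pair
#' statistic with ties counted 1/2), in percent. A class absent from the
#' true labels gets `NA`.
#'
#' @param scores n x n_classes score matrix (columns in `class_names`
#'   order).
#' @param true_labels true class per row.
#' @param class_names ordered class vocabulary.
#' @return named vector of per-class AUC percentages.
#' @export
roc_auc <- function(scores, true_labels,
                    class_names = colnames(scores)) {
  scores <- as.matrix(scores)
  if (is.null(class_names)) class_names <- sort(unique(true_labels))
  stopifnot(ncol(scores) == length(class_names),
            nrow(scores) == length(true_labels))
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  out <- vapply(seq_along(class_names), function(k) {
    pos <- true_labels == class_names[k]
    if (!any(pos) || all(pos)) return(NA_real_)
    rc <- roc_curve(scores[, k], pos)
    100 * trapezoid_auc(rc$fpr, rc$tpr)
  }, numeric(1))
  stats::setNames(out, class_names)
}

#' Macro average of per-class metric values
#'
#' Unweighted arithmetic mean over classes (the report's "average ratio"
#' row). Rounding to table precision is a display concern; see
#' [round_half_up()].
#'
#' @param per_class_values one value per class, no missing entries.
#' @return the unweighted mean.
#' @export
macro_average <- function(per_class_values) {
  if (length(per_class_values) == 0L || anyNA(per_class_values))
    stop("one value per class required (no missing values)", call. = FALSE)
  mean(per_class_values)
}

#' Round half away from zero
#'
#' Display rounding used in report tables (2 decimals, half-up), applied
#' only at presentation time.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded values.
#' @export
round_half_up <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Full metrics report
#'
#' Per-class sensitivity, precision, accuracy, specificity and (when
#' scores are supplied) AUC, together with their macro averages and the
#' micro accuracy (trace / total).
#'
#' @param cm a [confusion()] matrix.
#' @param scores optional n x n_classes score matrix for AUC.
#' @param true_labels true labels matching `scores` rows.
#' @return a `metrics_report`: list with `confusion`, `per_class`,
#'   `macro`, `micro_accuracy`.
#' @export
metrics_report <- function(cm, scores = NULL, true_labels = NULL) {
  pc <- per_class_metrics(cm)
  if (!is.null(scores)) {
    pc$auc <- unname(roc_auc(scores, true_labels, rownames(cm)))
  }
  macro <- vapply(pc[, -1, drop = FALSE],
                  function(v) if (anyNA(v)) NA_real_ else macro_average(v),
                  numeric(1))
  structure(list(confusion = cm, per_class = pc, macro = macro,
                 micro_accuracy = 100 * sum(diag(cm)) / sum(cm)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Confusion matrix (rows = true):\n")
  print(x$confusion)
  pc <- x$per_class
  pc[, -1] <- lapply(pc[, -1, drop = FALSE], round_half_up)
  cat("\nPer-class metrics (%):\n")
  print(pc, row.names = FALSE)
  cat("\nAverage ratio (%):\n")
  print(round_half_up(x$macro))
  cat("\nOverall accuracy: ", round_half_up(x$micro_accuracy), "%\n", sep = "")
  invisible(x)
}
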