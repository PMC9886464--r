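# One-vs-rest diagnostic metrics. Note the F1 convention: the harmonic
# mean of SPECIFICITY and sensitivity (not the precision-recall F1); the
# conventional F1 is available separately as f1_precision_recall().

#' Confusion matrix over the five diagnostic classes
#'
#' `counts[i, j]` is the number of recordings of true class i predicted as
#' class j, over the fixed class order AS, MR, MS, MVP, N.
#'
#' @param y_true,y_pred Equal-length label vectors over [PCG_CLASSES].
#' @param classes Class order (default [PCG_CLASSES]).
#' @return Integer matrix with class `pcg_confusion`.
#' @export
confusion_matrix <- function(y_true, y_pred, classes = PCG_CLASSES) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) == 0L)
    abort_validation("empty label vectors")
  if (length(y_true) != length(y_pred))
    abort_validation("y_true (%d) and y_pred (%d) differ in length",
                     length(y_true), length(y_pred))
  bad <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(bad))
    abort_validation("unknown label(s): %s", paste(bad, collapse = ", "))
  cm <- table(factor(y_true, levels = classes), factor(y_pred, levels = classes))
  m <- matrix(as.integer(cm), nrow = length(classes),
              dimnames = list(true = classes, predicted = classes))
  structure(m, class = c("pcg_confusion", class(m)))
}

#' One-vs-rest metrics for a target class
#'
#' Collapses the confusion matrix to target-vs-rest and reports, in
#' percent at full precision:
#' `accuracy = (TP + TN) / total`, `sensitivity = TP / (TP + FN)`,
#' `specificity = TN / (TN + FP)` and
#' `f1 = 2 * specificity * sensitivity / (specificity + sensitivity)`
#' (the harmonic mean of specificity and sensitivity). A metric with a
#' zero denominator is returned as `NA` with an `"undefined"` attribute
#' naming it, never silently as 0.
#'
#' @param cm A `pcg_confusion` (or plain square count matrix with class
#'   dimnames).
#' @param target Class to treat as positive.
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`,
#'   `f1` (percent), with attribute `counts` = `c(TP, FN, FP, TN)`.
#' @examples
#' cm <- confusion_matrix(c("AS", "AS", "N"), c("AS", "N", "N"))
#' class_metrics(cm, "AS")
#' @export
class_metrics <- function(cm, target) {
  cm <- as_count_matrix(cm)
  classes <- rownames(cm)
  if (!(target %in% classes))
    abort_validation("unknown target class '%s'", target)
  if (sum(cm[target, ]) < 1L)
    abort_validation("target class %s has no true recordings", target)
  tp <- cm[target, target]
  fn <- sum(cm[target, ]) - tp
  fp <- sum(cm[, target]) - tp
  tn <- sum(cm) - tp - fn - fp

  undefined <- character(0)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else { undefined <- c(undefined, "sensitivity"); NA_real_ }
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else { undefined <- c(undefined, "specificity"); NA_real_ }
  f1 <- if (!is.na(sens) && !is.na(spec) && sens + spec > 0)
    2 * spec * sens / (spec + sens)
  else { undefined <- c(undefined, "f1"); NA_real_ }
  out <- c(accuracy = 100 * (tp + tn) / sum(cm),
           sensitivity = sens, specificity = spec, f1 = f1)
  attr(out, "counts") <- c(TP = tp, FN = fn, FP = fp, TN = tn)
  if (length(undefined)) attr(out, "undefined") <- undefined
  out
}

as_count_matrix <- function(cm) {
  m <- unclass(cm)
  if (!is.matrix(m) || nrow(m) != ncol(m) || is.null(rownames(m)))
    abort_validation("cm must be a square count matrix with class dimnames")
  if (any(m < 0) || any(m != round(m)))
    abort_validation("cm entries must be non-negative integers")
  m
}

#' F1 from a sensitivity/specificity pair
#'
#' The harmonic-mean-of-specificity-and-sensitivity F1 used throughout the
#' metric tables, for worked-example arithmetic on printed percentages.
#'
#' @param sensitivity,specificity Percentages.
#' @return F1 in percent (full precision).
#' @examples
#' f1_spec_sens(100, 98.75)  # 99.37 after 2-decimal rounding
#' @export
f1_spec_sens <- function(sensitivity, specificity) {
  2 * specificity * sensitivity / (specificity + sensitivity)
}

#' Conventional precision-recall F1 for a target class
#'
#' Offered under a distinct name to avoid silent confusion with the
#' specificity-based [f1_spec_sens()] convention used in the main tables.
#'
#' @inheritParams class_metrics
#' @return F1 in percent.
#' @export
f1_precision_recall <- function(cm, target) {
  cm <- as_count_matrix(cm)
  tp <- cm[target, target]
  fn <- sum(cm[target, ]) - tp
  fp <- sum(cm[, target]) - tp
  if (2 * tp + fp + fn == 0) return(NA_real_)
  100 * 2 * tp / (2 * tp + fp + fn)
}

#' Macro-average metrics over the four disease classes
#'
#' Unweighted arithmetic mean of each metric over AS, MR, MS and MVP
#' (Normal excluded, matching the reporting convention for disease
#' diagnosis); pass `classes = PCG_CLASSES` for the all-5-class average.
#'
#' @param x A confusion matrix, or a list of per-class metric vectors from
#'   [class_metrics()] named by class.
#' @param classes Classes averaged over (default AS, MR, MS, MVP).
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`,
#'   `f1` (percent).
#' @export
macro_average <- function(x, classes = c("AS", "MR", "MS", "MVP")) {
  per_class <- if (is.list(x)) {
    missing <- setdiff(classes, names(x))
    if (length(missing))
      abort_validation("missing class metrics for %s", paste(missing, collapse = ", "))
    x[classes]
  } else {
    cm <- as_count_matrix(x)
    missing <- classes[rowSums(cm)[classes] < 1L]
    if (length(missing))
      abort_validation("class(es) %s absent from the confusion matrix",
                       paste(missing, collapse = ", "))
    lapply(classes, function(cl) class_metrics(cm, cl))
  }
  m <- do.call(rbind, lapply(per_class, function(v)
    v[c("accuracy", "sensitivity", "specificity", "f1")]))
  colMeans(m)
}

#' Metric report table
#'
#' One row per indicator, one column per class, rounded half-up to two
#' decimals for display (internals stay at full precision).
#'
#' @param cm A confusion matrix.
#' @param classes Column order (default [PCG_CLASSES]).
#' @return Data.frame with rownames accuracy/sensitivity/specificity/f1.
#' @export
metrics_table <- function(cm, classes = PCG_CLASSES) {
  cm <- as_count_matrix(cm)
  cols <- lapply(classes, function(cl) round_half_up(class_metrics(cm, cl), 2))
  out <- as.data.frame(do.call(cbind, cols))
  names(out) <- classes
  out
}

#' Check integer realizability of a printed sensitivity/specificity pair
#'
#' Given per-class positives and negatives, finds the integer one-vs-rest
#' counts (TP, FN, FP, TN) that reproduce the stated percentages, if they
#' exist: a sanity check that a reported metric table is jointly achievable
#' by an integer confusion matrix.
#'
#' @param sensitivity,specificity Percentages.
#' @param n_pos,n_neg True positives-class and rest-class totals.
#' @param tol Matching tolerance on the percentages after rounding
#'   (default 0.005, i.e. exact to the printed 2 decimals).
#' @return Named integer vector `c(TP, FN, FP, TN)`, or `NULL` if no
#'   integer counts reproduce the pair.
#' @export
ovr_counts <- function(sensitivity, specificity, n_pos, n_neg, tol = 0.005) {
  tp <- round(sensitivity / 100 * n_pos)
  tn <- round(specificity / 100 * n_neg)
  ok_tp <- abs(round_half_up(100 * tp / n_pos, 2) - sensitivity) <= tol
  ok_tn <- abs(round_half_up(100 * tn / n_neg, 2) - specificity) <= tol
  if (!ok_tp || !ok_tn) return(NULL)
  c(TP = tp, FN = n_pos - tp, FP = n_neg - tn, TN = tn)
}
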