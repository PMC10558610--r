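# Confusion-matrix screening diagnostics on the held-out test partition.

#' Threshold predicted probabilities into classes
#'
#' Prediction is positive when the probability is greater than or equal to
#' the threshold (so p = 0.5 at the default threshold is positive). The
#' threshold must lie strictly inside (0, 1).
#'
#' @param probabilities numeric vector in (0, 1).
#' @param threshold decision threshold, default 0.5.
#' @return integer 0/1 vector.
#' @export
classify <- function(probabilities, threshold = 0.5) {
  if (length(threshold) != 1 || !is.finite(threshold) ||
      threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly inside (0, 1)")
  }
  as.integer(probabilities >= threshold)
}

#' Confusion counts
#'
#' A true positive is a predicted-diabetic respondent who reports diabetes; a
#' false positive a predicted-diabetic who does not; a false negative a
#' predicted-non-diabetic who does.
#'
#' @param predictions,outcomes binary 0/1 vectors of equal length.
#' @return object of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`
#'   summing to the number of observations.
#' @export
confusion <- function(predictions, outcomes) {
  if (length(predictions) != length(outcomes)) stop("length mismatch")
  stopifnot(all(predictions %in% c(0, 1)), all(outcomes %in% c(0, 1)))
  structure(list(tp = sum(predictions == 1 & outcomes == 1),
                 fp = sum(predictions == 1 & outcomes == 0),
                 tn = sum(predictions == 0 & outcomes == 0),
                 fn = sum(predictions == 0 & outcomes == 1)),
            class = "confusion_counts")
}

#' Screening diagnostic rates
#'
#' Accuracy (tp+tn)/total; sensitivity tp/(tp+fn); specificity tn/(tn+fp);
#' false positive rate fp/(fp+tn) = 1 - specificity; false negative rate
#' fn/(fn+tp) = 1 - sensitivity. The false rates are rates (complements of
#' sensitivity/specificity), not proportions of all predictions. Rates whose
#' class is absent from the data are reported as NA, never as 0.
#'
#' @param counts a `confusion_counts` object.
#' @return object of class `diagnostic_report` with fields `accuracy`,
#'   `sensitivity`, `specificity`, `false_positive_rate`,
#'   `false_negative_rate`.
#' @export
diagnostic_report <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tp + counts$fp + counts$tn + counts$fn
  if (total == 0) stop("empty confusion table")
  pos <- counts$tp + counts$fn
  neg <- counts$tn + counts$fp
  sens <- if (pos > 0) counts$tp / pos else NA_real_
  spec <- if (neg > 0) counts$tn / neg else NA_real_
  structure(list(accuracy = (counts$tp + counts$tn) / total,
                 sensitivity = sens,
                 specificity = spec,
                 false_positive_rate = if (neg > 0) counts$fp / neg else NA_real_,
                 false_negative_rate = if (pos > 0) counts$fn / pos else NA_real_,
                 counts = counts),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, digits = 2, ...) {
  cat(sprintf("ACC %.*f | TP %.*f | TN %.*f | FP %.*f | FN %.*f\n",
              digits, x$accuracy, digits, x$sensitivity, digits, x$specificity,
              digits, x$false_positive_rate, digits, x$false_negative_rate))
  invisible(x)
}
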