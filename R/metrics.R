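#' Confusion summary
#'
#' @param tp,fp,tn,fn non-negative counts; at least one must be positive.
#' @return object of class `confusion_summary`.
#' @export
confusion_summary <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers", call. = FALSE)
  if (sum(counts) < 1)
    stop("confusion summary needs at least one count", call. = FALSE)
  counts <- as.list(stats::setNames(as.integer(counts), names(counts)))
  structure(counts, class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("<confusion_summary> TP=%d FP=%d TN=%d FN=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Sensitivity (true positive rate), in percent
#'
#' `100 * tp / (tp + fn)`.
#'
#' @param cs a [confusion_summary()].
#' @return percent.
#' @export
sensitivity <- function(cs) {
  stopifnot(inherits(cs, "confusion_summary"))
  if (cs$tp + cs$fn == 0)
    stop("sensitivity undefined: no positive samples", call. = FALSE)
  100 * cs$tp / (cs$tp + cs$fn)
}

#' Specificity (true negative rate), in percent
#'
#' `100 * tn / (tn + fp)`.
#'
#' @param cs a [confusion_summary()].
#' @return percent.
#' @export
specificity <- function(cs) {
  stopifnot(inherits(cs, "confusion_summary"))
  if (cs$tn + cs$fp == 0)
    stop("specificity undefined: no negative samples", call. = FALSE)
  100 * cs$tn / (cs$tn + cs$fp)
}

# half-up rounding as used in printed tables (round() is half-even and is
# additionally thrown off by binary representation, e.g. 90.795 -> 90.79)
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5 + 1e-7) / 10^digits
}

#' Accuracy rate (balanced accuracy), in percent
#'
#' The arithmetic mean of sensitivity and specificity, reported to two
#' decimals — the summary statistic used for the per-group screen accuracy.
#'
#' @param sens,spec sensitivity and specificity in percent.
#' @return percent, rounded to two decimals.
#' @export
accuracy_rate <- function(sens, spec) {
  stopifnot(sens >= 0, sens <= 100, spec >= 0, spec <= 100)
  round_half_up((sens + spec) / 2, 2)
}

#' False negative and false positive rates, in percent
#'
#' `(100 - sensitivity, 100 - specificity)`.
#'
#' @param sens,spec sensitivity and specificity in percent.
#' @return named numeric vector `c(fn_rate, fp_rate)`.
#' @export
false_rates <- function(sens, spec) {
  stopifnot(sens >= 0, sens <= 100, spec >= 0, spec <= 100)
  c(fn_rate = 100 - sens, fp_rate = 100 - spec)
}

#' Prediction rate, in percent
#'
#' `100 * n_pos / n_total`, rounded to two decimals.
#'
#' @param n_pos number of records called positive.
#' @param n_total total number of records (`>= 1`).
#' @return percent.
#' @export
prediction_rate <- function(n_pos, n_total) {
  if (n_total < 1 || n_pos < 0 || n_pos > n_total)
    stop("need 0 <= n_pos <= n_total and n_total >= 1", call. = FALSE)
  round_half_up(100 * n_pos / n_total, 2)
}
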