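# Confusion-matrix metrics with melanoma (label 1) as the positive class,
# and descriptive statistics over repeated optimization runs.

#' Confusion counts for binary predictions
#'
#' Melanoma (label 1) is the positive class throughout.
#'
#' @param y_true,y_pred equal-length vectors of 0/1 labels.
#' @return object of class `confusion_counts` with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred lengths differ (", length(y_true), " vs ",
         length(y_pred), ")")
  }
  if (length(y_true) == 0L) stop("no samples")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("labels must be 0 or 1")
  }
  structure(list(
    tp = sum(y_true == 1 & y_pred == 1),
    fp = sum(y_true == 0 & y_pred == 1),
    fn = sum(y_true == 1 & y_pred == 0),
    tn = sum(y_true == 0 & y_pred == 0)
  ), class = "confusion_counts")
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Zero-denominator conventions: precision, recall and F1 are 0 when
#' undefined (the behaviour reported for collapsed, constant-prediction
#' models).
#'
#' @param c a `confusion_counts`.
#' @return object of class `metrics_report` with `accuracy`, `precision`,
#'   `recall`, `f1`.
#' @export
compute_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  total <- c$tp + c$fp + c$fn + c$tn
  if (total == 0L) stop("no samples")
  precision <- if (c$tp + c$fp > 0) c$tp / (c$tp + c$fp) else 0
  recall <- if (c$tp + c$fn > 0) c$tp / (c$tp + c$fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(accuracy = (c$tp + c$tn) / total,
                 precision = precision, recall = recall, f1 = f1),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Descriptive statistics of final run fitnesses
#'
#' Minimum, maximum, mean, median and the sample (n - 1) standard deviation
#' of the final best fitness across independent optimization runs.
#'
#' @param final_fitnesses numeric vector, one value per run.
#' @return list with `min`, `max`, `mean`, `median`, `sd`, `n`.
#' @export
summarize_runs <- function(final_fitnesses) {
  if (length(final_fitnesses) < 1L) stop("no run fitnesses supplied")
  list(min = min(final_fitnesses), max = max(final_fitnesses),
       mean = mean(final_fitnesses), median = median(final_fitnesses),
       sd = if (length(final_fitnesses) > 1L) sd(final_fitnesses) else 0,
       n = length(final_fitnesses))
}

#' Pick the best, median and worst runs
#'
#' Sorts runs by final best fitness ascending (ties broken by run seed
#' ascending): best is the first, worst the last, and the median the
#' `ceiling(n / 2)`-th order statistic.
#'
#' @param runs list of `de_result` objects.
#' @return list with elements `best`, `median`, `worst` (each a `de_result`).
#' @export
pick_representatives <- function(runs) {
  if (length(runs) < 1L) stop("no runs supplied")
  fits <- vapply(runs, function(r) r$best$fitness, numeric(1))
  seeds <- vapply(runs, function(r) as.integer(r$seed), integer(1))
  ord <- order(fits, seeds)
  list(best = runs[[ord[1L]]],
       median = runs[[ord[ceiling(length(ord) / 2)]]],
       worst = runs[[ord[length(ord)]]])
}
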