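#' Confusion counts for SOZ contact classification
#'
#' SOZ is the positive class. Predictions may be probabilities (thresholded)
#' or already-binary labels.
#'
#' @param predictions numeric probabilities or 0/1 predictions.
#' @param labels binary reference labels.
#' @param threshold probability threshold.
#' @return Named integer vector `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(predictions, labels, threshold = 0.5) {
  if (length(predictions) != length(labels))
    stop("predictions and labels must have equal length")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  pred <- as.integer(predictions >= threshold)
  c(TP = sum(pred == 1L & labels == 1L),
    TN = sum(pred == 0L & labels == 0L),
    FP = sum(pred == 1L & labels == 0L),
    FN = sum(pred == 0L & labels == 1L))
}

#' Classification metrics in percent
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy, positive
#' and negative predictive value, all scaled to percent at full precision.
#' A zero denominator yields `NA` for that metric with a warning (never 0).
#'
#' @param counts named vector with `TP`, `TN`, `FP`, `FN`.
#' @return Named numeric vector `SEN`, `SPE`, `ACC`, `PPV`, `NPV`.
#' @export
soz_metrics <- function(counts) {
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator")
      return(NA_real_)
    }
    100 * num / den
  }
  c(SEN = safe(tp, tp + fn, "sensitivity"),
    SPE = safe(tn, tn + fp, "specificity"),
    ACC = safe(tp + tn, tp + tn + fp + fn, "accuracy"),
    PPV = safe(tp, tp + fp, "PPV"),
    NPV = safe(tn, tn + fn, "NPV"))
}

#' Aggregate per-patient metrics
#'
#' Unweighted arithmetic mean of each metric across patients; missing
#' (undefined) values are skipped with a message reporting how many.
#'
#' @param per_patient matrix or data frame, one row per patient, metric
#'   columns.
#' @return Named numeric vector of means.
#' @export
aggregate_metrics <- function(per_patient) {
  m <- as.matrix(per_patient)
  if (nrow(m) < 1L) stop("need at least one patient")
  n_missing <- sum(is.na(m))
  if (n_missing > 0L)
    message("aggregate_metrics: skipping ", n_missing, " undefined value(s)")
  colMeans(m, na.rm = TRUE)
}
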