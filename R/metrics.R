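#' Confusion counts from truth and prediction vectors
#'
#' @param truth,pred Integer 0/1 vectors of equal length (1 = ACP).
#' @return A `confusion_counts` list with fields `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, pred) {
  if (length(truth) != length(pred) || length(truth) == 0L)
    stop("truth and pred must be non-empty and of equal length", call. = FALSE)
  if (any(!truth %in% c(0L, 1L)) || any(!pred %in% c(0L, 1L)))
    stop("truth and pred must be 0/1", call. = FALSE)
  structure(list(TP = sum(truth == 1L & pred == 1L),
                 FP = sum(truth == 0L & pred == 1L),
                 TN = sum(truth == 0L & pred == 0L),
                 FN = sum(truth == 1L & pred == 0L)),
            class = "confusion_counts")
}

#' Binary classification metrics as percentages
#'
#' Computes accuracy, precision, sensitivity, specificity and the Matthews
#' correlation coefficient from confusion counts:
#' \deqn{ACC = (TP+TN)/(TP+TN+FP+FN)}
#' \deqn{PRE = TP/(TP+FP), \quad SN = TP/(TP+FN), \quad SP = TN/(TN+FP)}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' All five are scaled to percent, so the rates lie in \[0, 100\] and MCC in
#' \[-100, 100\]. A metric whose denominator is zero is reported as `NA`
#' (undefined) rather than silently zero, and the run continues.
#'
#' @param counts A [confusion_counts()] object, or a list with fields
#'   `TP`, `FP`, `TN`, `FN`.
#' @return Named numeric vector `c(ACC, PRE, SN, SP, MCC)` in percent.
#' @export
compute_metrics <- function(counts) {
  tp <- as.numeric(counts$TP); fp <- as.numeric(counts$FP)
  tn <- as.numeric(counts$TN); fn <- as.numeric(counts$FN)
  total <- tp + fp + tn + fn
  if (total == 0) stop("no samples", call. = FALSE)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  c(ACC = 100 * (tp + tn) / total,
    PRE = 100 * safe_div(tp, tp + fp),
    SN  = 100 * safe_div(tp, tp + fn),
    SP  = 100 * safe_div(tn, tn + fp),
    MCC = 100 * safe_div(tp * tn - fp * fn, mcc_den))
}
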