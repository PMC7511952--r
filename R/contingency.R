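#' Contingency metrics for a binary marker predicting pCR
#'
#' Builds the 2x2 confusion table of a marker call against pathological
#' complete response and derives the standard performance measures. The
#' positive class is pCR and marker-positive means "predicted pCR", so
#' `tp` counts marker-positive pCR samples, `fp` marker-positive non-pCR,
#' `fn` marker-negative pCR and `tn` marker-negative non-pCR. Any metric
#' whose denominator is zero is `NA` (undefined), never a division by zero.
#'
#' @param tp,fp,fn,tn non-negative integer cell counts, summing to > 0.
#' @return an object of class `"contingency_result"`: a list with the four
#'   counts, `n`, and exact fractions `sensitivity` (tp/(tp+fn)),
#'   `specificity` (tn/(tn+fp)), `ppv` (tp/(tp+fp)), `npv` (tn/(tn+fn)),
#'   `positive_rate` ((tp+fp)/n), `pcr_rate_overall` ((tp+fn)/n),
#'   `pcr_rate_marker_pos` (tp/(tp+fp)) and `pcr_rate_marker_neg`
#'   (fn/(fn+tn)).
#' @export
#' @examples
#' contingency_metrics(24, 6, 19, 79)  # ppv 0.800, sensitivity 0.558
contingency_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    abort_stage("contingency", "counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n == 0) abort_stage("contingency", "counts must sum to > 0")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn, n = n,
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    positive_rate = ratio(tp + fp, n),
    pcr_rate_overall = ratio(tp + fn, n),
    pcr_rate_marker_pos = ratio(tp, tp + fp),
    pcr_rate_marker_neg = ratio(fn, fn + tn)
  ), class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("2x2 marker-vs-pCR contingency (n =", x$n, ")\n")
  tab <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2,
                dimnames = list(marker = c("positive", "negative"),
                                outcome = c("pCR", "non-pCR")))
  print(tab)
  cat(sprintf("sensitivity %s  specificity %s  PPV %s  NPV %s\n",
              fmt_pct(x$sensitivity), fmt_pct(x$specificity),
              fmt_pct(x$ppv), fmt_pct(x$npv)))
  cat(sprintf("positive rate %s  pCR rate overall %s  pCR rate marker+ %s\n",
              fmt_pct(x$positive_rate), fmt_pct(x$pcr_rate_overall),
              fmt_pct(x$pcr_rate_marker_pos)))
  invisible(x)
}

#' @export
as.data.frame.contingency_result <- function(x, ...) {
  data.frame(tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn, n = x$n,
             sensitivity = x$sensitivity, specificity = x$specificity,
             ppv = x$ppv, npv = x$npv, positive_rate = x$positive_rate,
             pcr_rate_overall = x$pcr_rate_overall,
             pcr_rate_marker_pos = x$pcr_rate_marker_pos,
             pcr_rate_marker_neg = x$pcr_rate_marker_neg)
}
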