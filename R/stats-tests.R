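# Thin, contract-enforcing wrappers around the classical tests used at every
# validation step: Fisher's exact test for marker-by-outcome tables,
# Mann-Whitney U for group comparisons of continuous levels, Wilcoxon
# signed-rank for paired baseline/on-treatment changes. All p-values are
# two-sided; exact distributions are used whenever the sample sizes and tie
# structure permit, with the tie-corrected normal approximation otherwise.

#' Fisher exact association between a binary marker and pCR
#'
#' @param marker_calls named logical vector, one call per sample.
#' @param outcomes named logical vector of pCR outcomes over the same samples.
#' @return a list with `odds_table` (2x2 marker x outcome counts) and `p`
#'   (two-sided Fisher exact p-value).
#' @export
association_test_binary <- function(marker_calls, outcomes) {
  if (is.null(names(marker_calls)) || is.null(names(outcomes))) {
    if (length(marker_calls) != length(outcomes)) {
      abort_stage("stats", "marker calls and outcomes differ in length")
    }
  } else {
    if (!setequal(names(marker_calls), names(outcomes))) {
      abort_stage("stats", "marker calls and outcomes cover different samples")
    }
    marker_calls <- marker_calls[names(outcomes)]
  }
  if (length(unique(outcomes)) < 2) {
    abort_stage("stats", "need at least one sample in each outcome group")
  }
  tab <- table(factor(marker_calls, levels = c(TRUE, FALSE)),
               factor(outcomes, levels = c(TRUE, FALSE)),
               dnn = c("marker", "pcr"))
  list(odds_table = unclass(tab),
       p = stats::fisher.test(tab, alternative = "two.sided")$p.value)
}

#' Mann-Whitney U comparison of a continuous level between pCR groups
#'
#' Exact enumeration of the rank distribution when group sizes and the tie
#' structure permit (no ties, both groups below 50), otherwise the
#' tie-corrected normal approximation with continuity correction.
#'
#' @param values numeric per-sample levels.
#' @param outcomes logical per-sample pCR indicators (same length/order, or
#'   both named by sample).
#' @return a list with `U` (the Mann-Whitney U statistic of the pCR group)
#'   and `p` (two-sided).
#' @export
group_compare_continuous <- function(values, outcomes) {
  if (!is.null(names(values)) && !is.null(names(outcomes))) {
    if (!setequal(names(values), names(outcomes))) {
      abort_stage("stats", "values and outcomes cover different samples")
    }
    values <- values[names(outcomes)]
  }
  x <- values[outcomes]
  y <- values[!outcomes]
  if (length(x) == 0 || length(y) == 0) {
    abort_stage("stats", "both outcome groups must be non-empty")
  }
  res <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  list(U = unname(res$statistic), p = res$p.value)
}

#' Wilcoxon signed-rank test for paired baseline/on-treatment values
#'
#' Zero differences are dropped before ranking (standard signed-rank
#' handling). If every difference is zero the test is vacuous: a warning is
#' issued and p = 1 is returned.
#'
#' @param baseline,on_treatment numeric vectors of paired measurements.
#' @return a list with `V` (signed-rank statistic) and `p` (two-sided).
#' @export
paired_change_test <- function(baseline, on_treatment) {
  if (length(baseline) != length(on_treatment)) {
    abort_stage("stats", "baseline and on-treatment vectors differ in length")
  }
  d <- baseline - on_treatment
  if (all(d == 0)) {
    warning("all paired differences are zero; signed-rank test is vacuous (p = 1)")
    return(list(V = NA_real_, p = 1))
  }
  res <- suppressWarnings(
    stats::wilcox.test(baseline, on_treatment, paired = TRUE,
                       alternative = "two.sided"))
  list(V = unname(res$statistic), p = res$p.value)
}
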