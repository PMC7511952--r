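# Paired baseline/on-treatment marker monitoring: delta-beta computation,
# large-decrease classification, the signed-rank change test, and the
# comparison of a selective marker against comparators (Ki-67 index, tumor
# size) that decrease regardless of outcome.

#' Change in a marker level between baseline and on-treatment biopsies
#'
#' Two conventions are supported because "delta-beta >= 50%" is ambiguous:
#' `absolute_points` (default) reports the drop in percentage points of the
#' methylation fraction, `(baseline - on_treatment) * 100`;
#' `relative_to_baseline` reports the drop as a percentage of the baseline
#' level, `(baseline - on_treatment) / baseline * 100` (requires
#' baseline > 0).
#'
#' @param baseline,on_treatment numeric fractions in \[0,1\] (vectorized).
#' @param convention `"absolute_points"` or `"relative_to_baseline"`.
#' @return numeric delta (positive = decrease).
#' @export
#' @examples
#' compute_delta(0.80, 0.20)                           # 60 points
#' compute_delta(0.80, 0.20, "relative_to_baseline")   # 75%
compute_delta <- function(baseline, on_treatment,
                          convention = c("absolute_points",
                                         "relative_to_baseline")) {
  convention <- match.arg(convention)
  assert_fraction(baseline, "baseline", "response")
  assert_fraction(on_treatment, "on_treatment", "response")
  if (convention == "absolute_points") {
    (baseline - on_treatment) * 100
  } else {
    if (any(baseline == 0)) {
      abort_stage("response",
                  "relative convention requires baseline > 0 for every pair")
    }
    (baseline - on_treatment) / baseline * 100
  }
}

#' Classify large on-treatment decreases of a marker
#'
#' A pair shows a large decrease when its delta (under the configured
#' convention) is at least `threshold` (inclusive >=). The summary reports
#' how many large-decrease samples achieved pCR. Both delta conventions are
#' reported per pair so the convention choice stays transparent.
#'
#' @param pairs `data.frame` with columns `sample_id`, `baseline`,
#'   `on_treatment`, `pcr`.
#' @param threshold delta threshold (default 50).
#' @param convention delta convention used for classification (default
#'   `"absolute_points"`; see [compute_delta()]).
#' @return a list with `classified` (the input plus `delta`,
#'   `delta_relative` where defined, `large_decrease`) and `summary`
#'   (`n_large`, `n_large_pcr`, `fraction_pcr`; `fraction_pcr` is `NA` when
#'   no pair is classified large).
#' @export
classify_large_decrease <- function(pairs, threshold = 50,
                                    convention = c("absolute_points",
                                                   "relative_to_baseline")) {
  convention <- match.arg(convention)
  if (nrow(pairs) == 0) {
    pairs$delta <- numeric(0); pairs$large_decrease <- logical(0)
    return(list(classified = pairs,
                summary = list(n_large = 0L, n_large_pcr = 0L,
                               fraction_pcr = NA_real_)))
  }
  delta_abs <- compute_delta(pairs$baseline, pairs$on_treatment,
                             "absolute_points")
  delta_rel <- ifelse(pairs$baseline > 0,
                      (pairs$baseline - pairs$on_treatment) /
                        pairs$baseline * 100,
                      NA_real_)
  delta <- if (convention == "absolute_points") delta_abs else {
    compute_delta(pairs$baseline, pairs$on_treatment, convention)
  }
  pairs$delta <- delta
  pairs$delta_relative <- delta_rel
  pairs$large_decrease <- delta >= threshold
  n_large <- sum(pairs$large_decrease)
  n_large_pcr <- sum(pairs$large_decrease & pairs$pcr)
  list(classified = pairs,
       summary = list(n_large = as.integer(n_large),
                      n_large_pcr = as.integer(n_large_pcr),
                      fraction_pcr = if (n_large == 0) NA_real_ else
                        n_large_pcr / n_large))
}

#' Compare response markers by outcome-selectivity of their decrease
#'
#' For each marker, the fraction of pCR and of non-pCR samples whose level
#' decreased at all, and whose level showed a large decrease, between
#' baseline and on-treatment. A useful response marker decreases selectively
#' in samples that achieve pCR; comparators like the Ki-67 index or tumor
#' size tend to decrease in most samples regardless of outcome.
#'
#' @param ... named paired `data.frame`s (columns `sample_id`, `baseline`,
#'   `on_treatment`, `pcr`), e.g.
#'   `compare_response_markers(methylation = pb, ki67 = pk)`. All must cover
#'   the same samples.
#' @param threshold large-decrease threshold (default 50).
#' @param convention delta convention (default `"absolute_points"`).
#' @return `data.frame` with one row per marker: `marker`,
#'   `consistency_in_pcr`, `consistency_in_nonpcr` (fractions with any
#'   decrease), `large_decrease_in_pcr`, `large_decrease_in_nonpcr`.
#' @export
compare_response_markers <- function(..., threshold = 50,
                                     convention = c("absolute_points",
                                                    "relative_to_baseline")) {
  convention <- match.arg(convention)
  markers <- list(...)
  if (length(markers) < 2 || is.null(names(markers)) ||
      any(names(markers) == "")) {
    abort_stage("response", "supply at least two named paired data frames")
  }
  ids <- lapply(markers, function(m) sort(m$sample_id))
  for (i in seq_along(markers)[-1]) {
    if (!identical(ids[[1]], ids[[i]])) {
      abort_stage("response", "markers cover different samples")
    }
  }
  do.call(rbind, lapply(names(markers), function(nm) {
    m <- markers[[nm]]
    dec <- m$baseline > m$on_treatment
    cls <- classify_large_decrease(m, threshold, convention)$classified
    frac <- function(flag, grp) {
      if (sum(grp) == 0) NA_real_ else sum(flag & grp) / sum(grp)
    }
    data.frame(marker = nm,
               consistency_in_pcr = frac(dec, m$pcr),
               consistency_in_nonpcr = frac(dec, !m$pcr),
               large_decrease_in_pcr = frac(cls$large_decrease, m$pcr),
               large_decrease_in_nonpcr = frac(cls$large_decrease, !m$pcr),
               stringsAsFactors = FALSE)
  }))
}
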