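# Marker dichotomization, marker combination, and the stratified
# Table-1-style performance report (methylation / ER / combined marker, by
# age group). The positive class is pCR throughout and a positive marker
# call means "predicted pCR".

#' Dichotomize continuous marker levels
#'
#' @param levels numeric per-sample fractions in \[0,1\] (e.g.
#'   pyrosequencing methylation levels).
#' @param threshold cutoff fraction. No default is shipped on purpose: the
#'   clinically calibrated cutoff is assay-specific and must be supplied.
#' @param comparator `"gt"` (level > threshold, default) or `"ge"`.
#' @return named logical vector of calls, with `threshold` and `comparator`
#'   attributes recording the rule.
#' @export
dichotomize <- function(levels, threshold, comparator = c("gt", "ge")) {
  comparator <- match.arg(comparator)
  assert_fraction(levels, "marker levels", "performance")
  if (missing(threshold) || is.null(threshold) || is.na(threshold)) {
    abort_stage("performance", "a dichotomization threshold must be supplied")
  }
  calls <- if (comparator == "gt") levels > threshold else levels >= threshold
  structure(calls, threshold = threshold, comparator = comparator)
}

#' Evaluate a binary marker against pCR outcomes
#'
#' @param samples a sample-sheet `data.frame` with `sample_id` and `pcr`.
#' @param calls logical marker calls named by sample id (or in row order).
#' @return a [contingency_metrics()] result.
#' @export
evaluate_marker <- function(samples, calls) {
  if (!is.null(names(calls))) {
    missing <- setdiff(samples$sample_id, names(calls))
    if (length(missing) > 0) {
      abort_stage("performance", "samples missing a marker call: ",
                  paste(missing, collapse = ", "))
    }
    calls <- calls[samples$sample_id]
  } else if (length(calls) != nrow(samples)) {
    abort_stage("performance", "one call per sample is required")
  }
  if (any(is.na(calls)) || any(is.na(samples$pcr))) {
    abort_stage("performance", "calls and pcr outcomes must be defined")
  }
  contingency_metrics(tp = sum(calls & samples$pcr),
                      fp = sum(calls & !samples$pcr),
                      fn = sum(!calls & samples$pcr),
                      tn = sum(!calls & !samples$pcr))
}

#' Combine two binary markers
#'
#' The published combined marker is methylation-high AND ER-negative.
#'
#' @param calls_a,calls_b logical call vectors over the same samples (named
#'   by sample id, or same length/order).
#' @param mode `"and"` (default) or `"or"`.
#' @return logical vector of combined calls.
#' @export
combine_markers <- function(calls_a, calls_b, mode = c("and", "or")) {
  mode <- match.arg(mode)
  if (!is.null(names(calls_a)) && !is.null(names(calls_b))) {
    if (!setequal(names(calls_a), names(calls_b))) {
      abort_stage("performance", "markers cover different samples")
    }
    calls_b <- calls_b[names(calls_a)]
  } else if (length(calls_a) != length(calls_b)) {
    abort_stage("performance", "marker call vectors differ in length")
  }
  if (mode == "and") calls_a & calls_b else calls_a | calls_b
}

stratum_membership <- function(ages, age_breaks) {
  if (length(age_breaks) == 0) {
    return(list(all = rep(TRUE, length(ages))))
  }
  if (length(age_breaks) != 2) {
    abort_stage("performance",
                "age_breaks must be empty or two values (low, high)")
  }
  lo <- age_breaks[1]; hi <- age_breaks[2]
  strata <- list(rep(TRUE, length(ages)),
                 ages > hi,
                 ages >= lo & ages <= hi,
                 ages < lo)
  names(strata) <- c("all", paste0(">", hi), paste0(lo, "-", hi),
                     paste0("<", lo))
  strata
}

#' Stratified marker performance report
#'
#' Evaluates the methylation marker, the ER-negative marker and their AND
#' combination overall and within age strata. With the default breaks
#' `c(45, 55)` the strata are `<45` (strict), `45-55` (inclusive both ends)
#' and `>55` (strict), which partition all ages. Rates are kept as exact
#' fractions internally; the print method renders 1-decimal percentages
#' (round-half-up).
#'
#' @param samples sample sheet with `sample_id`, `pcr`, `age`.
#' @param methylation_calls,er_calls logical call vectors (ER call = TRUE
#'   for ER-negative, the pCR-predicting state), named by sample id or in
#'   row order.
#' @param age_breaks numeric length-2 `c(low, high)` or `numeric(0)` for an
#'   overall-only report.
#' @return object of class `"stratified_report"`: list of strata, each with
#'   `label`, `n`, and [contingency_metrics()] results for `methylation`,
#'   `er` and `combined`.
#' @export
stratified_report <- function(samples, methylation_calls, er_calls,
                              age_breaks = c(45, 55)) {
  if (any(is.na(samples$age))) {
    abort_stage("performance", "age must be present for every sample")
  }
  align <- function(calls) {
    if (!is.null(names(calls))) calls[samples$sample_id] else calls
  }
  meth <- align(methylation_calls)
  er <- align(er_calls)
  comb <- combine_markers(meth, er, "and")
  strata <- stratum_membership(samples$age, age_breaks)
  out <- lapply(names(strata), function(lab) {
    keep <- strata[[lab]]
    sub <- samples[keep, , drop = FALSE]
    list(label = lab, n = nrow(sub),
         methylation = evaluate_marker(sub, unname(meth[keep])),
         er = evaluate_marker(sub, unname(er[keep])),
         combined = evaluate_marker(sub, unname(comb[keep])))
  })
  names(out) <- names(strata)
  structure(list(strata = out, age_breaks = age_breaks),
            class = "stratified_report")
}

#' @export
print.stratified_report <- function(x, ...) {
  cat("Marker performance by age stratum (positive class = pCR)\n")
  for (s in x$strata) {
    cat(sprintf("\n[%s] n = %d, pCR rate %s\n", s$label, s$n,
                fmt_pct(s$methylation$pcr_rate_overall)))
    for (m in c("methylation", "er", "combined")) {
      cr <- s[[m]]
      cat(sprintf("  %-11s pos rate %-6s sens %-6s spec %-6s PPV %-6s (tp %d fp %d fn %d tn %d)\n",
                  m, fmt_pct(cr$positive_rate), fmt_pct(cr$sensitivity),
                  fmt_pct(cr$specificity), fmt_pct(cr$ppv),
                  cr$tp, cr$fp, cr$fn, cr$tn))
    }
  }
  invisible(x)
}

#' @export
as.data.frame.stratified_report <- function(x, ...) {
  do.call(rbind, lapply(x$strata, function(s) {
    do.call(rbind, lapply(c("methylation", "er", "combined"), function(m) {
      cbind(stratum = s$label, marker = m, as.data.frame(s[[m]]))
    }))
  })) -> df
  rownames(df) <- NULL
  df
}

#' Reference HER2-positive neoadjuvant cohort (reconstructed counts)
#'
#' A 128-patient sample sheet reconstructed from published per-stratum
#' marker-by-outcome counts of a HER2-positive breast cancer neoadjuvant
#' trastuzumab-plus-chemotherapy cohort: methylation-high, ER-negative and
#' combined-marker (methylation-high AND ER-negative) margins by outcome in
#' age strata <45, 45-55 and >55. The joint (methylation x ER) assignment
#' within each stratum-by-outcome cell is the deterministic one implied by
#' the combined marker being the AND of the two (synthetic reconstruction:
#' per-patient rows are not the original records, but every published
#' margin is reproduced exactly).
#'
#' @return a `data.frame` with columns `sample_id`, `cohort_set`, `pcr`,
#'   `er_status`, `age`, `timepoint`, plus the marker call column
#'   `meth_high`.
#' @export
her2_reference_cohort <- function() {
  # per stratum x outcome: n, methylation-high, ER-negative, combined(high & neg)
  cells <- rbind(
    data.frame(stratum = ">55",   age = 60, pcr = TRUE,  n = 28, meth = 22, erneg = 23, comb = 18),
    data.frame(stratum = ">55",   age = 60, pcr = FALSE, n = 46, meth = 8,  erneg = 19, comb = 5),
    data.frame(stratum = "45-55", age = 50, pcr = TRUE,  n = 9,  meth = 5,  erneg = 6,  comb = 3),
    data.frame(stratum = "45-55", age = 50, pcr = FALSE, n = 18, meth = 1,  erneg = 7,  comb = 1),
    data.frame(stratum = "<45",   age = 40, pcr = TRUE,  n = 6,  meth = 3,  erneg = 6,  comb = 3),
    data.frame(stratum = "<45",   age = 40, pcr = FALSE, n = 21, meth = 1,  erneg = 4,  comb = 0)
  )
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    c_ <- cells[i, ]
    n_hp <- c_$meth - c_$comb        # meth-high, ER-positive
    n_ln <- c_$erneg - c_$comb       # meth-low, ER-negative
    n_lp <- c_$n - c_$comb - n_hp - n_ln
    stopifnot(n_hp >= 0, n_ln >= 0, n_lp >= 0)
    data.frame(
      stratum = c_$stratum, age = c_$age, pcr = c_$pcr,
      meth_high = rep(c(TRUE, TRUE, FALSE, FALSE),
                      times = c(c_$comb, n_hp, n_ln, n_lp)),
      er_status = rep(c("negative", "positive", "negative", "positive"),
                      times = c(c_$comb, n_hp, n_ln, n_lp)),
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  data.frame(
    sample_id = sprintf("ref%03d", seq_len(nrow(df))),
    cohort_set = "validation",
    pcr = df$pcr,
    er_status = df$er_status,
    age = df$age,
    timepoint = "baseline",
    meth_high = df$meth_high,
    stringsAsFactors = FALSE
  )
}
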