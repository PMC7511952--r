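# Expression normalization and the volcano screen for genes differentially
# expressed between pCR and non-pCR samples, followed by an abundance gate.

#' Normalize an expression matrix to the 75th-percentile-zero convention
#'
#' Signal intensities are log2-transformed and each sample (column) is
#' shifted so that its 75th percentile (linear-interpolation quantile,
#' R type 7) is exactly 0. A matrix that already satisfies the convention
#' (per-sample 75th percentile within 1e-9 of 0) is returned unchanged, so
#' normalization is idempotent.
#'
#' @param raw numeric gene-by-sample matrix of strictly positive raw
#'   intensities (or an already-normalized matrix, returned as is).
#' @return normalized log2-scale matrix of the same shape.
#' @export
#' @examples
#' m <- matrix(c(1, 2, 4, 8), ncol = 1,
#'             dimnames = list(paste0("g", 1:4), "s1"))
#' normalize_expression(m)  # log2 values 0..3 centred on their 75th pct 2.25
normalize_expression <- function(raw) {
  if (!is.matrix(raw) || !is.numeric(raw)) {
    abort_stage("expression", "input must be a numeric matrix")
  }
  if (any(!is.finite(raw))) {
    abort_stage("expression", "input contains non-finite values")
  }
  p75 <- apply(raw, 2, stats::quantile, probs = 0.75, type = 7, names = FALSE)
  if (all(abs(p75) <= 1e-9)) return(raw)  # already normalized
  if (any(raw <= 0)) {
    abort_stage("expression", "raw intensities must be strictly positive")
  }
  logged <- log2(raw)
  p75 <- apply(logged, 2, stats::quantile, probs = 0.75, type = 7, names = FALSE)
  sweep(logged, 2, p75, "-")
}

welch_p <- function(x, y) {
  # zero-variance groups make t.test error; identical constant groups carry
  # no evidence (p = 1), constant groups at different levels are maximally
  # separated (p -> 0)
  out <- tryCatch(stats::t.test(x, y, var.equal = FALSE)$p.value,
                  error = function(e) NA_real_)
  if (is.na(out)) out <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
  out
}

#' Volcano screen for differential expression between pCR groups
#'
#' Per gene, the log2 fold change is the difference of group means of the
#' normalized log intensities (pCR minus non-pCR) and the p-value comes from
#' a two-sample test on those intensities (Welch's t by default,
#' Mann-Whitney selectable). A gene is selected when p < `p_threshold` and
#' its linear fold change `2^|log2_fc|` exceeds `fc_threshold`. No
#' multiple-testing correction is applied; the raw-p gate is the screen.
#'
#' @param expr normalized gene-by-sample matrix (see
#'   [normalize_expression()]).
#' @param outcomes logical pCR indicator per sample (named by sample id or
#'   in column order).
#' @param p_threshold raw p-value gate (default 0.001).
#' @param fc_threshold linear fold-change gate (default 4, strict >).
#' @param test `"welch"` (default) or `"mannwhitney"`.
#' @return a `data.frame` with one row per gene: `gene_id`, `log2_fc`, `p`,
#'   `mean_intensity` (grand mean of normalized intensity over all samples),
#'   `selected`, `direction` (up_in_pcr/down_in_pcr).
#' @export
volcano_screen <- function(expr, outcomes, p_threshold = 0.001,
                           fc_threshold = 4, test = c("welch", "mannwhitney")) {
  test <- match.arg(test)
  if (!is.null(names(outcomes))) {
    if (!setequal(names(outcomes), colnames(expr))) {
      abort_stage("expression", "outcome names do not match expression samples")
    }
    outcomes <- outcomes[colnames(expr)]
  }
  if (sum(outcomes) < 2 || sum(!outcomes) < 2) {
    abort_stage("expression", "need at least 2 samples per outcome group")
  }
  xp <- expr[, outcomes, drop = FALSE]
  xn <- expr[, !outcomes, drop = FALSE]
  log2_fc <- rowMeans(xp) - rowMeans(xn)
  p <- vapply(seq_len(nrow(expr)), function(i) {
    if (test == "welch") {
      welch_p(xp[i, ], xn[i, ])
    } else {
      suppressWarnings(stats::wilcox.test(xp[i, ], xn[i, ])$p.value)
    }
  }, numeric(1))
  data.frame(
    gene_id = rownames(expr),
    log2_fc = unname(log2_fc),
    p = p,
    mean_intensity = unname(rowMeans(expr)),
    selected = p < p_threshold & 2^abs(log2_fc) > fc_threshold,
    direction = ifelse(log2_fc >= 0, "up_in_pcr", "down_in_pcr"),
    stringsAsFactors = FALSE
  )
}

#' Abundance filter on volcano-selected genes
#'
#' Keeps the selected genes whose average normalized intensity over all
#' samples exceeds the threshold (strict >), preserving input order.
#'
#' @param results a volcano `data.frame` from [volcano_screen()].
#' @param intensity_threshold average normalized log-intensity gate
#'   (default 0.5).
#' @return character vector of retained gene ids.
#' @export
abundance_filter <- function(results, intensity_threshold = 0.5) {
  results$gene_id[results$selected &
                    results$mean_intensity > intensity_threshold]
}
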