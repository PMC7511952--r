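# Somatic-variant filtering by six evidence rules and copy-number calls from
# normalized targeted-panel coverage. The rules are applied with their
# strict/inclusive boundaries taken literally: tumor VAF > 10%, normal
# VAF < 1%, homopolymer length < 3, >= 5 alternate reads on each strand,
# coverage > 100 reads, and a protein-altering or splice consequence.

FILTER_RULES <- c("tumor_vaf", "normal_vaf", "homopolymer",
                  "strand_support", "coverage", "consequence")
PASSING_CONSEQUENCES <- c("missense", "nonsense", "frameshift", "splice")

# vectorized rule evaluation over a variant table; returns a logical matrix
# (variants x rules), TRUE where the rule FAILED
failed_rule_matrix <- function(df, strand_rule = c("per_strand", "total")) {
  strand_rule <- match.arg(strand_rule)
  strand_fail <- if (strand_rule == "per_strand") {
    pmin(df$fwd_alt, df$rev_alt) < 5
  } else {
    (df$fwd_alt + df$rev_alt) < 5 | df$fwd_alt < 1 | df$rev_alt < 1
  }
  cbind(
    tumor_vaf      = !(df$tumor_vaf > 0.10),
    normal_vaf     = !(df$normal_vaf < 0.01),
    homopolymer    = !(df$homopolymer_len < 3),
    strand_support = strand_fail,
    coverage       = !(df$coverage > 100),
    consequence    = !(df$consequence %in% PASSING_CONSEQUENCES)
  )
}

#' Classify one variant against the six functional-mutation rules
#'
#' A variant is retained as a functional somatic mutation when all of:
#' tumor VAF > 10%, normal VAF < 1%, homopolymer length < 3, at least 5
#' alternate-supporting reads on each strand, coverage > 100 reads, and its
#' consequence is protein-altering or splice-affecting (missense, nonsense,
#' frameshift or splice). Every violated rule is reported, not just the
#' first.
#'
#' @param v a single variant: a list or one-row `data.frame` with fields
#'   `tumor_vaf`, `normal_vaf`, `homopolymer_len`, `fwd_alt`, `rev_alt`,
#'   `coverage`, `consequence`.
#' @param strand_rule `"per_strand"` (default: >= 5 alt reads on each
#'   strand) or `"total"` (>= 5 alt reads overall with >= 1 on each strand).
#' @return a list with `passed` (logical) and `failed_rules` (character
#'   vector, empty iff passed).
#' @export
#' @examples
#' classify_variant(list(tumor_vaf = 0.15, normal_vaf = 0.005,
#'                       homopolymer_len = 2, fwd_alt = 6, rev_alt = 7,
#'                       coverage = 250, consequence = "missense"))
classify_variant <- function(v, strand_rule = c("per_strand", "total")) {
  df <- as.data.frame(v[c("tumor_vaf", "normal_vaf", "homopolymer_len",
                          "fwd_alt", "rev_alt", "coverage", "consequence")],
                      stringsAsFactors = FALSE)
  failed <- failed_rule_matrix(df, strand_rule)[1, ]
  list(passed = !any(failed), failed_rules = names(failed)[failed])
}

#' Filter a variant table by the six rules
#'
#' @param table a variant `data.frame` (see [read_variant_table()] for the
#'   column contract).
#' @inheritParams classify_variant
#' @return a list with `retained` (passing rows, input order preserved) and
#'   `decisions` (a `data.frame` with `passed` and a semicolon-joined
#'   `failed_rules` column per input row).
#' @export
filter_variants <- function(table, strand_rule = c("per_strand", "total")) {
  if (nrow(table) == 0) {
    return(list(retained = table,
                decisions = data.frame(passed = logical(0),
                                       failed_rules = character(0))))
  }
  validate_variant_table(table)
  fails <- failed_rule_matrix(table, strand_rule)
  passed <- rowSums(fails) == 0
  decisions <- data.frame(
    passed = passed,
    failed_rules = apply(fails, 1, function(f) paste(FILTER_RULES[f], collapse = ";")),
    stringsAsFactors = FALSE
  )
  if (!is.null(table$variant_id)) decisions$variant_id <- table$variant_id
  list(retained = table[passed, , drop = FALSE], decisions = decisions)
}

#' Copy-number gain/loss calls from tumor/normal panel coverage
#'
#' The average read depth of each target region is normalized by the
#' sample's total reads; the fold change is the ratio of the tumor's
#' normalized depth to the matched normal's. Fold changes > 2 are called
#' gains and < 0.5 losses. A region with zero normal depth but non-zero
#' tumor depth is a gain with infinite fold change; zero in both is neutral
#' with undefined (NA) fold change.
#'
#' @param tumor_depths,normal_depths named numeric vectors of mean region
#'   depths over the same regions.
#' @param tumor_total,normal_total total read counts of the two samples
#'   (default: sum of the region depths).
#' @param gain_threshold,loss_threshold fold-change cutoffs (defaults 2 and
#'   0.5).
#' @param sample_id optional sample label carried into the output.
#' @return a `data.frame` with `region_id`, `fold_change` and `state`
#'   (gain/neutral/loss).
#' @export
call_copy_number <- function(tumor_depths, normal_depths,
                             tumor_total = sum(tumor_depths),
                             normal_total = sum(normal_depths),
                             gain_threshold = 2, loss_threshold = 0.5,
                             sample_id = NULL) {
  if (any(tumor_depths < 0) || any(normal_depths < 0)) {
    abort_stage("cnv", "region depths must be non-negative")
  }
  if (tumor_total <= 0 || normal_total <= 0) {
    abort_stage("cnv", "total read counts must be positive")
  }
  if (!is.null(names(tumor_depths)) && !is.null(names(normal_depths))) {
    if (!setequal(names(tumor_depths), names(normal_depths))) {
      abort_stage("cnv", "tumor and normal cover different regions")
    }
    normal_depths <- normal_depths[names(tumor_depths)]
  } else if (length(tumor_depths) != length(normal_depths)) {
    abort_stage("cnv", "tumor and normal depth vectors differ in length")
  }
  fold <- (tumor_depths / tumor_total) / (normal_depths / normal_total)
  fold[normal_depths == 0 & tumor_depths > 0] <- Inf
  fold[normal_depths == 0 & tumor_depths == 0] <- NA_real_
  state <- rep("neutral", length(fold))
  state[!is.na(fold) & fold > gain_threshold] <- "gain"
  state[!is.na(fold) & fold < loss_threshold] <- "loss"
  out <- data.frame(
    region_id = names(tumor_depths) %||% paste0("region", seq_along(fold)),
    fold_change = unname(fold),
    state = state,
    stringsAsFactors = FALSE
  )
  if (!is.null(sample_id)) out <- cbind(sample_id = sample_id, out)
  rownames(out) <- NULL
  out
}
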