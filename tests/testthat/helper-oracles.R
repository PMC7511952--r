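# Independent brute-force oracles: exhaustive enumerations kept deliberately
# separate from the implementation paths they check.

# Two-sided Mann-Whitney p by enumerating all C(n1+n2, n1) group assignments
# of the pooled values (assumes no ties). U = #{(i,j): x_i > y_j}.
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_stat <- function(a, b) sum(outer(a, b, ">"))
  u_obs <- u_stat(x, y)
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Two-sided Wilcoxon signed-rank p by enumerating all 2^n sign assignments
# of the absolute differences (zeros removed beforehand; assumes no ties in
# |d|). V = sum of ranks of positive differences.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  p_le <- mean(vs <= v_obs)
  p_ge <- mean(vs >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Two-sided Fisher exact p for a 2x2 table by summing the probabilities of
# every table with the same margins whose probability does not exceed the
# observed one. Probabilities from binomial coefficients directly.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  prob <- function(aa) {
    exp(lchoose(r1, aa) + lchoose(r2, c1 - aa) - lchoose(n, c1))
  }
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, prob, numeric(1))
  p_obs <- prob(a)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Contingency metrics recomputed by expanding counts to per-sample labels
# and recounting from scratch.
oracle_contingency <- function(tp, fp, fn, tn) {
  call <- rep(c(TRUE, TRUE, FALSE, FALSE), times = c(tp, fp, fn, tn))
  pcr  <- rep(c(TRUE, FALSE, TRUE, FALSE), times = c(tp, fp, fn, tn))
  n <- length(call)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(sensitivity = ratio(sum(call & pcr), sum(pcr)),
       specificity = ratio(sum(!call & !pcr), sum(!pcr)),
       ppv = ratio(sum(call & pcr), sum(call)),
       npv = ratio(sum(!call & !pcr), sum(!call)),
       positive_rate = ratio(sum(call), n),
       pcr_rate_overall = ratio(sum(pcr), n))
}

# Per-site classifier metrics by explicit confusion-matrix counting.
oracle_site_metrics <- function(betas, outcomes, beta_cut, direction) {
  meth <- betas > beta_cut
  predicted_pcr <- if (direction == "hyper_in_pcr") meth else !meth
  acc <- mean(predicted_pcr == outcomes)
  neg_class <- if (direction == "hyper_in_pcr") !outcomes else outcomes
  spec <- sum(!meth & neg_class) / sum(neg_class)
  list(accuracy = acc, specificity = spec)
}

# small valid variant record used as the base of many variant tests
base_variant <- function(...) {
  utils::modifyList(list(sample_id = "s1", gene = "G1", chrom = "chr1",
                         pos = 100L, ref = "A", alt = "G", tumor_vaf = 0.15,
                         normal_vaf = 0.005, homopolymer_len = 2L,
                         fwd_alt = 6L, rev_alt = 7L, coverage = 250L,
                         consequence = "missense"),
                    list(...))
}
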