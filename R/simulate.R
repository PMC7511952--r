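# Seeded synthetic cohorts with the statistical structure the pipeline
# assumes: a planted run of consecutive hypermethylated probes enriched in
# pCR samples, normal reference profiles drawn from the unmethylated
# background, planted fold-change genes in the expression matrix, a
# boundary-case variant table, planted copy-number gains/losses, and paired
# baseline/on-treatment marker levels that decay selectively in responders.
#
# One master seed controls everything through derive_seed(seed, label), so
# each sub-generator (and each cohort set) is independently reproducible.

beta_shapes <- function(mean, concentration = 20) {
  c(shape1 = mean * concentration, shape2 = (1 - mean) * concentration)
}

#' Configuration of a synthetic cohort
#'
#' Defaults mirror an Infinium-style methylation screening cohort of a
#' HER2-positive neoadjuvant trial at desk scale: 14 pCR vs 20 non-pCR
#' screening samples, 10,000 probes, a planted marker region of 4
#' consecutive probes hypermethylated (mean beta 0.6 against a 0.05
#' background) in 80% of pCR and 2% of non-pCR samples, 10 differentially
#' expressed genes at log2 fold change 2.5, and an 80% on-treatment decay
#' of the marker level in responders. The non-pCR penetrance default is
#' calibrated so the planted site clears the specificity gate (> 0.85,
#' i.e. at most 2 of 20 non-pCR samples methylated) with probability
#' `pbinom(2, 20, 0.02)` = 0.993 per cohort; the published cohort-wide
#' methylation-high rate in non-responders (~12%) can be emulated by
#' raising `penetrance_nonpcr`, at the cost of frequent specificity-gate
#' misses at this cohort size.
#'
#' @param seed master integer seed.
#' @param n_pcr,n_nonpcr cohort sizes by outcome.
#' @param n_probes,n_genes array sizes.
#' @param marker_region list: `n_consecutive_probes` (>= 1),
#'   `beta_methylated_mean`, `beta_background_mean`, `penetrance_pcr`,
#'   `penetrance_nonpcr` (all fractions).
#' @param de_genes list: `count`, `log2_fold_change`.
#' @param responder_delta_fraction fraction of the baseline marker level
#'   lost on treatment in pCR samples.
#' @param expression_noise_sd per-observation log2-scale noise sd.
#' @return a validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 1, n_pcr = 14, n_nonpcr = 20,
                              n_probes = 10000, n_genes = 2000,
                              marker_region = list(),
                              de_genes = list(),
                              responder_delta_fraction = 0.8,
                              expression_noise_sd = 0.3) {
  mr <- utils::modifyList(list(n_consecutive_probes = 4,
                               beta_methylated_mean = 0.6,
                               beta_background_mean = 0.05,
                               penetrance_pcr = 0.8,
                               penetrance_nonpcr = 0.02), marker_region)
  de <- utils::modifyList(list(count = 10, log2_fold_change = 2.5), de_genes)
  stopifnot(mr$n_consecutive_probes >= 1, n_pcr >= 1, n_nonpcr >= 1,
            n_probes >= mr$n_consecutive_probes, n_genes >= de$count)
  assert_fraction(c(mr$beta_methylated_mean, mr$beta_background_mean,
                    mr$penetrance_pcr, mr$penetrance_nonpcr,
                    responder_delta_fraction), "config fractions", "simulate")
  structure(list(seed = as.integer(seed), n_pcr = n_pcr, n_nonpcr = n_nonpcr,
                 n_probes = n_probes, n_genes = n_genes, marker_region = mr,
                 de_genes = de,
                 responder_delta_fraction = responder_delta_fraction,
                 expression_noise_sd = expression_noise_sd),
            class = "simulation_config")
}

#' Simulate a synthetic cohort bundle
#'
#' Generates every input the pipeline consumes. Background probes draw from
#' a low-mode beta distribution (mean `beta_background_mean`); the planted
#' region's probes draw from a high-mode distribution (mean
#' `beta_methylated_mean`) in "methylated" samples, a state assigned with
#' probability `penetrance_pcr` in pCR and `penetrance_nonpcr` in non-pCR
#' samples. Reference profiles (one mammary-epithelial-like and two
#' leukocyte-like) draw from the background everywhere. Expression raw
#' intensities are log-normal with the planted genes shifted by
#' `log2_fold_change` in pCR samples. Paired marker levels decay by
#' `responder_delta_fraction` on treatment in pCR samples and stay flat (up
#' to noise) otherwise; a Ki-67-like comparator decays in every sample.
#'
#' @param config a [simulation_config()].
#' @param cohort_set `"screening"`, `"validation"` or `"revalidation"`;
#'   enters the seed derivation, so the three sets of one master seed are
#'   disjoint draws.
#' @return a list with `samples`, `beta`, `annotation`, `reference`,
#'   `expression` (raw positive intensities), `variants`, `coverage`,
#'   `paired_beta`, `paired_ki67`, `planted` (ids of the planted signals)
#'   and `config`.
#' @export
simulate_cohort <- function(config = simulation_config(),
                            cohort_set = c("screening", "validation",
                                           "revalidation")) {
  cohort_set <- match.arg(cohort_set)
  mr <- config$marker_region
  if (mr$penetrance_pcr <= mr$penetrance_nonpcr) {
    warning("penetrance_pcr <= penetrance_nonpcr: the planted marker is ",
            "undetectable by design")
  }
  seed_for <- function(label) derive_seed(config$seed,
                                          paste0(cohort_set, ":", label))
  n <- config$n_pcr + config$n_nonpcr

  # --- samples ------------------------------------------------------------
  set.seed(seed_for("samples"))
  ids <- sprintf("%s%03d", substr(cohort_set, 1, 3), seq_len(n))
  pcr <- c(rep(TRUE, config$n_pcr), rep(FALSE, config$n_nonpcr))
  er_neg <- stats::rbinom(n, 1, ifelse(pcr, 0.8, 0.35)) == 1
  samples <- data.frame(
    sample_id = ids, cohort_set = cohort_set, pcr = pcr,
    er_status = ifelse(er_neg, "negative", "positive"),
    age = sample(30:75, n, replace = TRUE),
    timepoint = "baseline", stringsAsFactors = FALSE
  )

  # --- probe annotation ---------------------------------------------------
  set.seed(seed_for("annotation"))
  probes_per_region <- max(5L, mr$n_consecutive_probes + 1L)
  n_regions <- ceiling(config$n_probes / probes_per_region)
  region_of <- rep(seq_len(n_regions), each = probes_per_region,
                   length.out = config$n_probes)
  within_idx <- stats::ave(seq_len(config$n_probes), region_of,
                           FUN = seq_along)
  planted_region <- max(1L, n_regions %/% 2L)
  region_class <- sample(c("cpg_island", "genic", "intergenic"), n_regions,
                         replace = TRUE, prob = c(0.35, 0.3, 0.35))
  region_class[planted_region] <- "cpg_island"
  region_chrom <- paste0("chr", (seq_len(n_regions) - 1) %% 22 + 1)
  region_gene <- ifelse(region_class == "intergenic", "",
                        sprintf("G%05d", seq_len(n_regions)))
  annotation <- data.frame(
    probe_id = sprintf("cg%07d", seq_len(config$n_probes)),
    chrom = region_chrom[region_of],
    pos = region_of * 100000L + within_idx * 100L,
    gene = region_gene[region_of],
    region_class = region_class[region_of],
    region_id = sprintf("reg%05d", region_of),
    stringsAsFactors = FALSE
  )
  planted_probes <- annotation$probe_id[
    region_of == planted_region & within_idx <= mr$n_consecutive_probes]

  # --- beta matrix + references -------------------------------------------
  set.seed(seed_for("beta"))
  bg <- beta_shapes(mr$beta_background_mean)
  hi <- beta_shapes(mr$beta_methylated_mean)
  beta <- matrix(stats::rbeta(config$n_probes * n, bg[1], bg[2]),
                 nrow = config$n_probes,
                 dimnames = list(annotation$probe_id, ids))
  methylated <- stats::rbinom(n, 1, ifelse(pcr, mr$penetrance_pcr,
                                           mr$penetrance_nonpcr)) == 1
  if (any(methylated)) {
    beta[planted_probes, methylated] <-
      stats::rbeta(length(planted_probes) * sum(methylated), hi[1], hi[2])
  }
  set.seed(seed_for("reference"))
  reference <- matrix(stats::rbeta(config$n_probes * 3, bg[1], bg[2]),
                      nrow = config$n_probes,
                      dimnames = list(annotation$probe_id,
                                      c("HMEC_like", "leukocyte1",
                                        "leukocyte2")))

  # --- expression ---------------------------------------------------------
  set.seed(seed_for("expression"))
  gene_ids <- sprintf("EX%05d", seq_len(config$n_genes))
  de_count <- config$de_genes$count
  lfc <- config$de_genes$log2_fold_change
  mu <- stats::runif(config$n_genes, 4, 10)
  de_idx <- seq_len(de_count)
  mu[de_idx] <- 10.5  # abundant, so planted genes clear the intensity gate
  shift <- matrix(0, config$n_genes, n)
  n_up <- ceiling(de_count / 2)
  shift[de_idx[seq_len(n_up)], pcr] <- lfc
  if (de_count > n_up) {
    shift[de_idx[(n_up + 1):de_count], pcr] <- -lfc
  }
  log_expr <- mu + shift +
    matrix(stats::rnorm(config$n_genes * n, 0, config$expression_noise_sd),
           config$n_genes, n)
  expression <- 2^log_expr
  dimnames(expression) <- list(gene_ids, ids)

  # --- variants + coverage ------------------------------------------------
  variants <- simulate_variant_boundary_cases()
  variants$sample_id <- ids[1]
  set.seed(seed_for("coverage"))
  n_cnv <- 50
  normal_depth <- round(stats::runif(n_cnv, 150, 400))
  fold <- rep(1, n_cnv)
  gain_regions <- c(3, 4); loss_regions <- c(7, 8)
  fold[gain_regions] <- 3; fold[loss_regions] <- 0.3
  tumor_depth <- round(normal_depth * fold *
                         exp(stats::rnorm(n_cnv, 0, 0.05)))
  coverage <- data.frame(region_id = sprintf("cnvR%02d", seq_len(n_cnv)),
                         tumor_depth = tumor_depth,
                         normal_depth = normal_depth,
                         stringsAsFactors = FALSE)

  # --- paired on-treatment marker levels ----------------------------------
  set.seed(seed_for("paired"))
  baseline_level <- pmin(pmax(colMeans(beta[planted_probes, , drop = FALSE]) +
                                stats::rnorm(n, 0, 0.02), 0), 1)
  on_treatment <- ifelse(pcr,
                         baseline_level * (1 - config$responder_delta_fraction),
                         baseline_level) + stats::rnorm(n, 0, 0.02)
  paired_beta <- data.frame(sample_id = ids,
                            baseline = unname(baseline_level),
                            on_treatment = pmin(pmax(on_treatment, 0), 1),
                            pcr = pcr, stringsAsFactors = FALSE)
  ki_base <- stats::runif(n, 0.3, 0.9)
  paired_ki67 <- data.frame(sample_id = ids,
                            baseline = ki_base,
                            on_treatment = ki_base *
                              stats::runif(n, 0.2, 0.6),
                            pcr = pcr, stringsAsFactors = FALSE)

  list(samples = samples, beta = beta, annotation = annotation,
       reference = reference, expression = expression, variants = variants,
       coverage = coverage, paired_beta = paired_beta,
       paired_ki67 = paired_ki67,
       planted = list(region_id = sprintf("reg%05d", planted_region),
                      probe_ids = planted_probes,
                      methylated_samples = ids[methylated],
                      de_genes = gene_ids[de_idx],
                      gain_regions = coverage$region_id[gain_regions],
                      loss_regions = coverage$region_id[loss_regions]),
       config = config)
}

#' Fixed boundary-case variant table for the six filter rules
#'
#' Fourteen records: for each of the six rules, one record failing exactly
#' that rule at its boundary value (e.g. coverage exactly 100, which the
#' strict `> 100` rule rejects) and one failing it clearly, all other rules
#' satisfied; plus one record passing every rule and one failing all six.
#' Exactly one record (`all_pass`) survives [filter_variants()].
#'
#' @return a variant `data.frame` with an extra `variant_id` column naming
#'   each case.
#' @export
simulate_variant_boundary_cases <- function() {
  base <- list(sample_id = "s1", gene = "TP53", chrom = "chr17",
               pos = 7577120L, ref = "C", alt = "T",
               tumor_vaf = 0.15, normal_vaf = 0.005, homopolymer_len = 2L,
               fwd_alt = 6L, rev_alt = 7L, coverage = 250L,
               consequence = "missense")
  make <- function(variant_id, ...) {
    rec <- utils::modifyList(base, list(...))
    as.data.frame(c(list(variant_id = variant_id), rec),
                  stringsAsFactors = FALSE)
  }
  tab <- rbind(
    make("tumor_vaf_boundary", tumor_vaf = 0.10),
    make("tumor_vaf_clear",    tumor_vaf = 0.02),
    make("normal_vaf_boundary", normal_vaf = 0.01),
    make("normal_vaf_clear",    normal_vaf = 0.05),
    make("homopolymer_boundary", homopolymer_len = 3L),
    make("homopolymer_clear",    homopolymer_len = 8L),
    make("strand_boundary", fwd_alt = 4L, rev_alt = 5L),
    make("strand_clear",    fwd_alt = 0L, rev_alt = 20L),
    make("coverage_boundary", coverage = 100L),
    make("coverage_clear",    coverage = 30L),
    make("consequence_boundary", consequence = "synonymous"),
    make("consequence_clear",    consequence = "noncoding"),
    make("all_pass"),
    make("all_fail", tumor_vaf = 0.05, normal_vaf = 0.02,
         homopolymer_len = 5L, fwd_alt = 1L, rev_alt = 2L, coverage = 50L,
         consequence = "synonymous")
  )
  rownames(tab) <- NULL
  tab
}

#' Write a simulated cohort bundle to a directory of TSV files
#'
#' @param bundle output of [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly; files `samples.tsv`, `beta.tsv`,
#'   `annotation.tsv`, `reference.tsv`, `expression.tsv`, `variants.tsv`,
#'   `coverage.tsv`, `paired_beta.tsv`, `paired_ki67.tsv`.
#' @export
write_cohort_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_sample_sheet(bundle$samples, p("samples.tsv"))
  write_beta_matrix(bundle$beta, p("beta.tsv"), bundle$annotation,
                    p("annotation.tsv"))
  write_beta_matrix(bundle$reference, p("reference.tsv"))
  write_expression_matrix(bundle$expression, p("expression.tsv"))
  utils::write.table(bundle$variants, p("variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$coverage, p("coverage.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$paired_beta, p("paired_beta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$paired_ki67, p("paired_ki67.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
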