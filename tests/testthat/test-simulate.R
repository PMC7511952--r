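test_that("simulation is byte-identical for a fixed seed and diverges across seeds", {
  cfg <- simulation_config(seed = 1, n_probes = 500, n_genes = 100)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  c_ <- simulate_cohort(simulation_config(seed = 2, n_probes = 500,
                                          n_genes = 100))
  expect_false(identical(a$beta, c_$beta))
  # cohort sets of one master seed are disjoint draws
  v <- simulate_cohort(cfg, "validation")
  expect_false(identical(a$beta[1:10, 1:5], v$beta[1:10, 1:5]))
})

test_that("generated values respect their range and structure contracts", {
  b <- simulate_cohort(simulation_config(seed = 3, n_probes = 800,
                                         n_genes = 150))
  expect_true(all(b$beta >= 0 & b$beta <= 1))
  expect_true(all(b$reference >= 0 & b$reference <= 1))
  expect_true(all(b$expression > 0))
  expect_true(all(b$paired_beta$baseline >= 0 & b$paired_beta$baseline <= 1))
  expect_silent(validate_beta_matrix(b$beta))
  # annotation contract: shared region -> shared chromosome, unique loci
  expect_silent(methmarker:::validate_annotation(b$annotation))
  # planted probes are consecutive members of one region
  ann <- b$annotation[b$annotation$probe_id %in% b$planted$probe_ids, ]
  expect_equal(unique(ann$region_id), b$planted$region_id)
  expect_equal(ann$pos, sort(ann$pos))
  # normalizing the simulated expression honours the percentile convention
  norm <- normalize_expression(b$expression)
  p75 <- apply(norm, 2, quantile, probs = 0.75, type = 7)
  expect_true(all(abs(p75) <= 1e-9))
  expect_equal(normalize_expression(norm), norm)
})

test_that("a noiseless-separation configuration classifies perfectly", {
  # penetrance 1 vs 0: every pCR sample methylated, no non-pCR sample is
  cfg <- simulation_config(seed = 7, n_probes = 400,
                           marker_region = list(penetrance_pcr = 1,
                                                penetrance_nonpcr = 0))
  b <- simulate_cohort(cfg)
  outcomes <- setNames(b$samples$pcr, b$samples$sample_id)
  expect_setequal(b$planted$methylated_samples,
                  b$samples$sample_id[b$samples$pcr])
  sites <- screen_sites(b$beta[b$planted$probe_ids, ], outcomes, all = TRUE)
  expect_true(all(sites$accuracy > 0.9))
  expect_equal(sites$specificity, rep(1, nrow(sites)))

  # the separation limit proper, free of sampling noise
  beta_sep <- matrix(rep(c(0.8, 0.05), times = c(14, 20)), nrow = 1,
                     dimnames = list("p1", b$samples$sample_id))
  m <- screen_sites(beta_sep, outcomes, all = TRUE)
  expect_equal(m$accuracy, 1)
  expect_equal(m$specificity, 1)
})

test_that("degenerate penetrance configurations warn", {
  cfg <- simulation_config(seed = 1, n_probes = 200,
                           marker_region = list(penetrance_pcr = 0.1,
                                                penetrance_nonpcr = 0.1))
  expect_warning(simulate_cohort(cfg), "undetectable")
})

test_that("the boundary variant table is built as named", {
  tab <- simulate_variant_boundary_cases()
  expect_equal(nrow(tab), 14)
  expect_equal(tab$coverage[tab$variant_id == "coverage_boundary"], 100L)
  expect_equal(tab$tumor_vaf[tab$variant_id == "tumor_vaf_boundary"], 0.10)
  expect_equal(tab$homopolymer_len[tab$variant_id == "homopolymer_boundary"], 3L)
  single_fail <- grepl("_(boundary|clear)$", tab$variant_id)
  expect_equal(sum(single_fail), 12)
  expect_silent(methmarker:::validate_variant_table(tab))
})

test_that("bundles round-trip through their TSV representation", {
  dir <- withr::local_tempdir()
  b <- simulate_cohort(simulation_config(seed = 9, n_probes = 300,
                                         n_genes = 80))
  write_cohort_bundle(b, dir)
  got <- methmarker:::read_cohort_bundle(dir)
  expect_equal(got$samples, b$samples)
  expect_equal(got$beta, b$beta, tolerance = 1e-12)
  expect_equal(got$annotation, b$annotation)
  expect_equal(got$variants$variant_id, b$variants$variant_id)
  expect_equal(got$paired_beta$baseline, b$paired_beta$baseline,
               tolerance = 1e-12)
})
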