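ref_matrix <- function(rows) {
  m <- do.call(rbind, rows)
  rownames(m) <- paste0("p", seq_along(rows))
  colnames(m) <- c("hmec", "leuk1", "leuk2")
  m
}

test_that("the unmethylated universe keeps probes below the gate in every reference", {
  ref <- ref_matrix(list(c(0.05, 0.10, 0.15),
                         c(0.05, 0.25, 0.10),
                         c(0.20, 0.10, 0.10)))
  expect_equal(select_unmethylated_universe(ref), "p1")  # 0.2 excluded: strict <
  expect_error(select_unmethylated_universe(ref[, 0, drop = FALSE]),
               "reference")
})

test_that("site classifier metrics match the hand-counted confusion table", {
  betas <- c(0.6, 0.5, 0.1, 0.7, 0.1, 0.05, 0.4, 0.1)
  outcomes <- rep(c(TRUE, FALSE), each = 4)
  m <- site_classifier_metrics(betas, outcomes, direction = "hyper_in_pcr")
  expect_equal(m$accuracy, 6 / 8)
  expect_equal(m$specificity, 3 / 4)

  sep <- site_classifier_metrics(c(0.8, 0.8, 0.05, 0.05),
                                 c(TRUE, TRUE, FALSE, FALSE),
                                 direction = "hyper_in_pcr")
  expect_equal(sep$accuracy, 1)
  expect_equal(sep$specificity, 1)

  zero <- site_classifier_metrics(rep(0, 8), outcomes,
                                  direction = "hyper_in_pcr")
  expect_equal(zero$accuracy, mean(!outcomes))
  expect_equal(zero$specificity, 1)
})

test_that("classifier metrics equal brute-force recounts on random inputs", {
  set.seed(41)
  for (i in 1:40) {
    n <- sample(4:50, 1)
    outcomes <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(outcomes)) < 2) next
    betas <- runif(n)
    for (dir in c("hyper_in_pcr", "hyper_in_nonpcr")) {
      got <- site_classifier_metrics(betas, outcomes, direction = dir)
      want <- oracle_site_metrics(betas, outcomes, 0.3, dir)
      expect_equal(got$accuracy, want$accuracy)
      expect_equal(got$specificity, want$specificity)
    }
  }
})

test_that("screen_sites separates planted from background probes", {
  b <- simulate_cohort(simulation_config(seed = 1))
  outcomes <- setNames(b$samples$pcr, b$samples$sample_id)
  universe <- select_unmethylated_universe(b$reference)
  beta_u <- b$beta[intersect(rownames(b$beta), universe), ]
  sites <- screen_sites(beta_u, outcomes)
  expect_true(all(b$planted$probe_ids %in% sites$probe_id))
  background_pass <- setdiff(sites$probe_id, b$planted$probe_ids)
  expect_lt(length(background_pass) / nrow(beta_u), 0.01)

  expect_equal(nrow(screen_sites(beta_u, outcomes, acc_threshold = 1.01)), 0)
  everything <- screen_sites(beta_u, outcomes, acc_threshold = 0,
                             spec_threshold = 0)
  expect_equal(nrow(everything), nrow(beta_u))
})

test_that("screen_sites flips every direction under outcome-label swap", {
  set.seed(43)
  beta <- matrix(runif(200), nrow = 20,
                 dimnames = list(paste0("p", 1:20), paste0("s", 1:10)))
  outcomes <- rep(c(TRUE, FALSE), each = 5)
  a <- screen_sites(beta, outcomes, acc_threshold = 0.5, spec_threshold = 0.5)
  b <- screen_sites(beta, !outcomes, acc_threshold = 0.5, spec_threshold = 0.5)
  expect_setequal(a$probe_id, b$probe_id)
  b <- b[match(a$probe_id, b$probe_id), ]
  flipped <- ifelse(a$direction == "hyper_in_pcr", "hyper_in_nonpcr",
                    "hyper_in_pcr")
  expect_equal(b$direction, flipped)
})

test_that("annotation filter keeps CpG-island and genic sites only", {
  sites <- data.frame(probe_id = c("p1", "p2", "p3"),
                      direction = "hyper_in_pcr", accuracy = 0.9,
                      specificity = 0.9, passed = TRUE)
  ann <- data.frame(probe_id = c("p1", "p2", "p3"), chrom = "chr1",
                    pos = c(1, 2, 3) * 100, gene = c("G1", "", "G2"),
                    region_class = c("cpg_island", "intergenic", "genic"),
                    region_id = c("r1", "r2", "r3"))
  expect_equal(annotation_filter(sites, ann)$probe_id, c("p1", "p3"))
  expect_equal(nrow(annotation_filter(sites[0, ], ann)), 0)
  expect_error(annotation_filter(data.frame(probe_id = "px"), ann), "px")
})

make_region_sites <- function(directions, region = "r1") {
  ids <- paste0("p", seq_along(directions))
  ann <- data.frame(probe_id = ids, chrom = "chr1",
                    pos = seq_along(directions) * 100, gene = "G1",
                    region_class = "cpg_island", region_id = region)
  keep <- !is.na(directions)
  sites <- data.frame(probe_id = ids[keep], direction = directions[keep],
                      accuracy = 0.9, specificity = 0.9, passed = TRUE)
  list(sites = sites, ann = ann)
}

test_that("consecutive-probe aggregation obeys adjacency and direction rules", {
  all5 <- make_region_sites(rep("hyper_in_pcr", 5))
  res <- aggregate_regions(all5$sites, all5$ann)
  expect_equal(nrow(res), 1)
  expect_equal(res$n_consecutive, 5)
  expect_equal(res$direction, "hyper_in_pcr")

  gap <- make_region_sites(c("hyper_in_pcr", "hyper_in_pcr", NA,
                             "hyper_in_pcr", "hyper_in_pcr"))
  expect_equal(nrow(aggregate_regions(gap$sites, gap$ann)), 0)  # runs of 2
  # allowing one intervening non-passing probe joins the runs
  res_gap <- aggregate_regions(gap$sites, gap$ann, max_gap = 1)
  expect_equal(nrow(res_gap), 1)
  expect_equal(res_gap$n_consecutive, 4)

  mixed <- make_region_sites(c("hyper_in_pcr", "hyper_in_pcr",
                               "hyper_in_nonpcr", "hyper_in_pcr"))
  expect_equal(nrow(aggregate_regions(mixed$sites, mixed$ann)), 0)
  res_mixed <- aggregate_regions(mixed$sites, mixed$ann, min_consecutive = 2)
  expect_equal(nrow(res_mixed), 1)
  expect_equal(res_mixed$direction, "hyper_in_pcr")
  expect_equal(res_mixed$n_consecutive, 2)
})

test_that("aggregation is invariant to probe order and region renaming", {
  set.seed(5)
  all4 <- make_region_sites(rep("hyper_in_pcr", 4))
  res <- aggregate_regions(all4$sites, all4$ann)
  perm <- sample(nrow(all4$sites))
  res_perm <- aggregate_regions(all4$sites[perm, ],
                                all4$ann[sample(nrow(all4$ann)), ])
  expect_equal(res_perm$probes, res$probes)
  renamed <- all4
  renamed$ann$region_id <- "zzz"
  res_ren <- aggregate_regions(renamed$sites, renamed$ann)
  expect_equal(res_ren$probes, res$probes)
  expect_equal(res_ren$n_consecutive, res$n_consecutive)
})

test_that("marker-level validation reproduces the exact Mann-Whitney p", {
  res <- validate_marker_levels(c(0.6, 0.5, 0.7, 0.1, 0.2, 0.15),
                                rep(c(TRUE, FALSE), each = 3))
  expect_equal(res$p, 0.1)
  same <- validate_marker_levels(c(0.3, 0.4, 0.3, 0.4),
                                 c(TRUE, TRUE, FALSE, FALSE))
  expect_gt(same$p, 0.9)
})

test_that("the full screen recovers the planted region and flips with penetrances", {
  b <- simulate_cohort(simulation_config(seed = 1))
  outcomes <- setNames(b$samples$pcr, b$samples$sample_id)
  screen <- screen_methylation_markers(b$beta, b$annotation, b$reference,
                                       outcomes)
  expect_true(b$planted$region_id %in% screen$regions$region_id)
  hit <- screen$regions[screen$regions$region_id == b$planted$region_id, ]
  expect_equal(hit$direction, "hyper_in_pcr")
  expect_gte(hit$n_consecutive, 3)
  f <- screen$funnel
  expect_true(f["universe"] <= f["probes_total"])
  expect_true(f["sites_passed"] <= f["universe"])
  expect_true(f["sites_annotated"] <= f["sites_passed"])

  swapped <- simulation_config(seed = 1, marker_region = list(
    penetrance_pcr = 0.02, penetrance_nonpcr = 0.8))
  bs <- suppressWarnings(simulate_cohort(swapped))
  screen_s <- screen_methylation_markers(
    bs$beta, bs$annotation, bs$reference,
    setNames(bs$samples$pcr, bs$samples$sample_id))
  hit_s <- screen_s$regions[screen_s$regions$region_id == bs$planted$region_id, ]
  expect_equal(hit_s$direction, "hyper_in_nonpcr")

  # marker levels on a validation cohort separate the outcome groups
  bv <- simulate_cohort(simulation_config(seed = 1, n_pcr = 17,
                                          n_nonpcr = 30), "validation")
  lv <- predict(screen, bv$beta)[hit$marker_id, ]
  expect_lt(validate_marker_levels(lv, bv$samples$pcr)$p, 0.05)
  calls <- predict(screen, bv$beta, type = "call")
  expect_type(calls[1, 1], "logical")
})
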