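test_that("each filter rule pins its strict/inclusive boundary", {
  pass <- classify_variant(base_variant())
  expect_true(pass$passed)
  expect_length(pass$failed_rules, 0)

  cases <- list(
    list(args = list(tumor_vaf = 0.10), rule = "tumor_vaf"),
    list(args = list(tumor_vaf = 0.101), rule = NULL),
    list(args = list(normal_vaf = 0.01), rule = "normal_vaf"),
    list(args = list(normal_vaf = 0.009), rule = NULL),
    list(args = list(homopolymer_len = 3L), rule = "homopolymer"),
    list(args = list(homopolymer_len = 2L), rule = NULL),
    list(args = list(fwd_alt = 4L, rev_alt = 9L), rule = "strand_support"),
    list(args = list(fwd_alt = 5L, rev_alt = 5L), rule = NULL),
    list(args = list(coverage = 100L), rule = "coverage"),
    list(args = list(coverage = 101L), rule = NULL),
    list(args = list(consequence = "synonymous"), rule = "consequence"),
    list(args = list(consequence = "splice"), rule = NULL)
  )
  for (case in cases) {
    got <- classify_variant(do.call(base_variant, case$args))
    if (is.null(case$rule)) {
      expect_true(got$passed, info = paste(names(case$args), collapse = ","))
    } else {
      expect_false(got$passed)
      expect_equal(got$failed_rules, case$rule)
    }
  }
})

test_that("the alternative total-strand rule is selectable", {
  v <- base_variant(fwd_alt = 1L, rev_alt = 8L)
  expect_false(classify_variant(v)$passed)
  expect_true(classify_variant(v, strand_rule = "total")$passed)
  v0 <- base_variant(fwd_alt = 0L, rev_alt = 20L)
  expect_false(classify_variant(v0, strand_rule = "total")$passed)
})

test_that("classification is monotone in every evidence field", {
  set.seed(17)
  weaken <- list(
    function(v) { v$tumor_vaf <- v$tumor_vaf * runif(1); v },
    function(v) { v$normal_vaf <- min(1, v$normal_vaf + runif(1, 0, 0.1)); v },
    function(v) { v$homopolymer_len <- v$homopolymer_len + sample(1:3, 1); v },
    function(v) { v$fwd_alt <- max(0L, v$fwd_alt - sample(1:5, 1)); v },
    function(v) { v$rev_alt <- max(0L, v$rev_alt - sample(1:5, 1)); v },
    function(v) { v$coverage <- max(v$fwd_alt + v$rev_alt,
                                    v$coverage - sample(1:200, 1)); v }
  )
  for (i in 1:50) {
    v <- base_variant(tumor_vaf = runif(1), normal_vaf = runif(1, 0, 0.05),
                      homopolymer_len = sample(0:5, 1),
                      fwd_alt = sample(0:10, 1), rev_alt = sample(0:10, 1),
                      coverage = sample(80:300, 1),
                      consequence = sample(c("missense", "synonymous"), 1))
    v$coverage <- max(v$coverage, v$fwd_alt + v$rev_alt)
    before <- classify_variant(v)$passed
    after <- classify_variant(weaken[[sample(length(weaken), 1)]](v))$passed
    if (!before) expect_false(after)
  }
})

test_that("filter_variants retains exactly the all-pass boundary record", {
  tab <- simulate_variant_boundary_cases()
  res <- filter_variants(tab)
  expect_equal(nrow(res$retained), 1)
  expect_equal(res$retained$variant_id, "all_pass")
  expect_equal(res$decisions$failed_rules[tab$variant_id == "coverage_boundary"],
               "coverage")
  expect_equal(tab$coverage[tab$variant_id == "coverage_boundary"], 100L)

  empty <- filter_variants(tab[0, ])
  expect_equal(nrow(empty$retained), 0)

  dup <- rbind(tab[tab$variant_id == "all_pass", ],
               tab[tab$variant_id == "all_pass", ])
  res2 <- filter_variants(dup)
  expect_equal(nrow(res2$retained), 2)
})

test_that("copy-number states follow the normalized fold-change thresholds", {
  cn <- call_copy_number(c(r1 = 500, r2 = 200, r3 = 90),
                         c(r1 = 200, r2 = 200, r3 = 200),
                         tumor_total = 1e6, normal_total = 1e6)
  expect_equal(cn$fold_change, c(2.5, 1.0, 0.45))
  expect_equal(cn$state, c("gain", "neutral", "loss"))

  zero <- call_copy_number(c(a = 10, b = 0), c(a = 0, b = 0),
                           tumor_total = 100, normal_total = 100)
  expect_equal(zero$state, c("gain", "neutral"))
  expect_equal(zero$fold_change, c(Inf, NA))

  expect_error(call_copy_number(c(a = -1), c(a = 2)), "non-negative")
})

test_that("copy-number calls are invariant under global depth scaling", {
  set.seed(19)
  t <- runif(20, 10, 500); n <- runif(20, 10, 500)
  names(t) <- names(n) <- paste0("r", 1:20)
  base <- call_copy_number(t, n, 1e6, 2e6)
  scaled <- call_copy_number(t * 7, n * 7, 7e6, 1.4e7)
  expect_equal(base$fold_change, scaled$fold_change)
  expect_equal(base$state, scaled$state)
})
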