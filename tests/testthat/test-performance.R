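test_that("dichotomization pins its comparator at the boundary", {
  calls <- dichotomize(c(0.4, 0.1), 0.15)
  expect_equal(unname(unclass(calls))[1:2], c(TRUE, FALSE))
  expect_equal(attr(calls, "threshold"), 0.15)
  expect_false(unname(dichotomize(0.15, 0.15))[1])
  expect_true(unname(dichotomize(0.15, 0.15, comparator = "ge"))[1])
  expect_true(all(dichotomize(c(0.3, 0.001), 0)))
  expect_error(dichotomize(c(0.5, 1.2), 0.15), "0,1")
  expect_error(dichotomize(0.5), "threshold")
})

test_that("marker combination is elementwise with AND-containment", {
  a <- c(s1 = TRUE, s2 = TRUE, s3 = FALSE)
  b <- c(s1 = TRUE, s2 = FALSE, s3 = FALSE)
  expect_equal(unname(combine_markers(a, b, "and")), c(TRUE, FALSE, FALSE))
  expect_equal(unname(combine_markers(a, b, "or")), c(TRUE, TRUE, FALSE))
  expect_equal(combine_markers(a, c(s1 = TRUE, s2 = TRUE, s3 = TRUE), "and"), a)
  expect_error(combine_markers(a, b[1:2]), "different samples")
  set.seed(47)
  x <- sample(c(TRUE, FALSE), 30, TRUE); y <- sample(c(TRUE, FALSE), 30, TRUE)
  expect_true(all(which(combine_markers(x, y, "and")) %in% which(x)))
})

test_that("the reconstructed reference cohort reproduces the published rates", {
  cohort <- her2_reference_cohort()
  expect_equal(nrow(cohort), 128)
  meth <- setNames(cohort$meth_high, cohort$sample_id)
  er <- setNames(cohort$er_status == "negative", cohort$sample_id)
  comb <- combine_markers(meth, er, "and")

  combined <- evaluate_marker(cohort, comb)
  expect_equal(round_half_up(100 * combined$ppv), 80.0)
  expect_equal(round_half_up(100 * combined$sensitivity), 55.8)
  expect_equal(round_half_up(100 * combined$specificity), 92.9)

  methylation <- evaluate_marker(cohort, meth)
  expect_equal(round_half_up(100 * methylation$positive_rate), 31.3)
  expect_equal(round_half_up(100 * methylation$pcr_rate_marker_pos), 75.0)
  expect_equal(round_half_up(100 * methylation$pcr_rate_overall), 33.6)

  er_cr <- evaluate_marker(cohort, er)
  expect_equal(round_half_up(100 * er_cr$positive_rate), 50.8)
})

test_that("all-negative calls give zero positive rate and undefined PPV", {
  cohort <- her2_reference_cohort()
  none <- setNames(rep(FALSE, nrow(cohort)), cohort$sample_id)
  cr <- evaluate_marker(cohort, none)
  expect_equal(cr$positive_rate, 0)
  expect_true(is.na(cr$ppv))
  expect_error(evaluate_marker(cohort, none[-1]), "ref001")
})

test_that("age strata partition the cohort and conserve counts", {
  cohort <- her2_reference_cohort()
  meth <- setNames(cohort$meth_high, cohort$sample_id)
  er <- setNames(cohort$er_status == "negative", cohort$sample_id)
  rep_ <- stratified_report(cohort, meth, er)
  expect_equal(names(rep_$strata), c("all", ">55", "45-55", "<45"))

  over55 <- rep_$strata[[">55"]]
  expect_equal(over55$n, 74)
  expect_equal(round_half_up(100 * over55$methylation$positive_rate), 40.5)
  expect_equal(round_half_up(100 * over55$methylation$pcr_rate_overall), 37.8)
  under45 <- rep_$strata[["<45"]]
  expect_equal(round_half_up(100 * under45$methylation$pcr_rate_overall), 22.2)

  for (m in c("methylation", "er", "combined")) {
    for (cell in c("tp", "fp", "fn", "tn")) {
      parts <- vapply(rep_$strata[c(">55", "45-55", "<45")],
                      function(s) s[[m]][[cell]], numeric(1))
      expect_equal(sum(parts), rep_$strata$all[[m]][[cell]],
                   info = paste(m, cell))
    }
  }

  overall_only <- stratified_report(cohort, meth, er, age_breaks = numeric(0))
  expect_equal(names(overall_only$strata), "all")
  expect_error(stratified_report(cohort, meth, er, age_breaks = c(40, 50, 60)),
               "age_breaks")
})

test_that("evaluate_marker equals a per-sample recount on random cohorts", {
  set.seed(53)
  for (i in 1:20) {
    n <- sample(5:500, 1)
    samples <- data.frame(sample_id = paste0("s", 1:n),
                          pcr = sample(c(TRUE, FALSE), n, TRUE))
    calls <- setNames(sample(c(TRUE, FALSE), n, TRUE), samples$sample_id)
    cr <- evaluate_marker(samples, calls)
    oc <- oracle_contingency(sum(calls & samples$pcr),
                             sum(calls & !samples$pcr),
                             sum(!calls & samples$pcr),
                             sum(!calls & !samples$pcr))
    expect_equal(cr$sensitivity, oc$sensitivity)
    expect_equal(cr$ppv, oc$ppv)
    expect_equal(cr$positive_rate, oc$positive_rate)
  }
})
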