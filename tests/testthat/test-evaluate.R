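test_that("Fisher exact p matches the brute-force enumeration oracle", {
  cases <- list(c(19, 0, 5, 3), c(1, 1, 1, 1), c(6, 1, 0, 4),
                c(0, 10, 10, 0), c(5, 0, 0, 5), c(2, 8, 7, 3))
  for (x in cases) {
    expect_equal(as.numeric(fisher_exact_2x2(x[1], x[2], x[3], x[4])),
                 brute_fisher(x[1], x[2], x[3], x[4]), tolerance = 1e-9)
  }
  # published-precision spot checks
  expect_equal(signif(fisher_exact_2x2(19, 0, 5, 3), 2), 0.019)
  expect_equal(signif(fisher_exact_2x2(6, 1, 0, 4), 2), 0.015)
  expect_equal(fisher_exact_2x2(1, 1, 1, 1), 1)
  # random property sweep
  set.seed(99)
  for (i in 1:60) {
    x <- as.vector(stats::rmultinom(1, sample(4:60, 1), rep(0.25, 4)))
    expect_equal(as.numeric(fisher_exact_2x2(x[1], x[2], x[3], x[4])),
                 brute_fisher(x[1], x[2], x[3], x[4]), tolerance = 1e-9)
  }
})

test_that("degenerate and invalid Fisher tables are handled", {
  p <- fisher_exact_2x2(0, 0, 3, 5)
  expect_equal(as.numeric(p), 1)
  expect_true(isTRUE(attr(p, "degenerate")))
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "empty")
})

test_that("confusion metrics reproduce published-style percentages", {
  r <- performance_from_counts(tp = 19, fp = 0, tn = 3, fn = 5)
  expect_equal(as_report_percent(r$sensitivity), 79)
  expect_equal(as_report_percent(r$specificity), 100)
  expect_equal(as_report_percent(r$accuracy), 81)
  expect_equal(as_report_p(r$fisher_p), 0.019)
  r2 <- performance_from_counts(tp = 28, fp = 2, tn = 3, fn = 6)
  expect_equal(as_report_percent(r2$accuracy), 79)
  expect_equal(as_report_percent(r2$sensitivity), 82)
  expect_equal(as_report_percent(r2$specificity), 60)
  # perfect classifier
  r3 <- performance_from_counts(tp = 10, fp = 0, tn = 0, fn = 0)
  expect_equal(r3$sensitivity, 1)
  expect_equal(r3$accuracy, 1)
})

test_that("swapping the label convention swaps sensitivity and specificity", {
  r <- performance_from_counts(tp = 12, fp = 3, tn = 20, fn = 4)
  rs <- performance_from_counts(tp = 20, fp = 4, tn = 12, fn = 3)
  expect_equal(r$sensitivity, rs$specificity)
  expect_equal(r$specificity, rs$sensitivity)
  expect_equal(r$accuracy, rs$accuracy)
})

test_that("concordance counts give the published-style summary", {
  r <- concordance_from_counts(cp = 41, dp = 24, cn = 345, dn = 13)
  expect_equal(as_report_percent(r$concordance), 91)
  r2 <- concordance_from_counts(cp = 54, dp = 74, cn = 254, dn = 1)
  expect_equal(as_report_percent(r2$concordance), 80)
  r3 <- concordance_from_counts(cp = 10, dp = 0, cn = 30, dn = 0)
  expect_equal(r3$concordance, 1)
})

test_that("reference scoring counts actives against the embedded panel", {
  cfg <- small_config(n = 500, seed = 17)
  lib <- generate_library(cfg)
  comp <- lib$compounds
  ref <- comp[comp$reference_label != "none", ]
  expect_equal(nrow(ref), 39)
  expect_equal(sum(ref$reference_label == "moderate_antagonist"), 6)
  expect_equal(sum(ref$reference_label == "negative"), 5)

  # synthetic calls straight from truth: agonists called active agonists
  mk_calls <- function(active_ids, active_outcome, assay) {
    data.table(sample_id = comp$compound_id,
               compound_id = comp$compound_id,
               assay_id = assay,
               outcome = ifelse(comp$compound_id %in% active_ids,
                                active_outcome, "inactive"),
               potency = NA_real_, efficacy = NA_real_)
  }
  ago_ids <- comp$compound_id[comp$er_dir_bla == "agonist"]
  calls <- mk_calls(ago_ids, "active_agonist", "bla_agonist")
  r <- reference_performance(calls, lib, "bla_agonist")
  expect_equal(r$fp, 0)
  expect_equal(r$tn, 5)
  expect_equal(r$tp + r$fn, sum(ref$reference_label %in%
    c("strong", "strong_moderate", "moderate", "weak", "very_weak")))
  expect_equal(r$sensitivity, 1)  # truth-derived calls catch every agonist

  ant_ids <- comp$compound_id[comp$er_dir_bla == "antagonist"]
  calls2 <- mk_calls(ant_ids, "active_antagonist", "bla_antagonist")
  r2 <- reference_performance(calls2, lib, "bla_antagonist")
  expect_equal(r2$tp, 6)
  expect_equal(r2$tn, 5)
  expect_equal(r2$tp + r2$fp + r2$tn + r2$fn, 11)
})

test_that("inconclusive reference calls are excluded or resolved by override", {
  cfg <- small_config(n = 500, seed = 17)
  lib <- generate_library(cfg)
  comp <- lib$compounds
  ref_ago <- comp$compound_id[comp$reference_label %in%
    c("strong", "strong_moderate", "moderate", "weak", "very_weak")]
  calls <- data.table(sample_id = comp$compound_id,
                      compound_id = comp$compound_id,
                      assay_id = "bla_agonist",
                      outcome = ifelse(comp$compound_id %in% ref_ago,
                                       "active_agonist", "inactive"),
                      potency = NA_real_, efficacy = NA_real_)
  calls[sample_id == ref_ago[1], outcome := "inconclusive_agonist_curve"]
  r_ex <- reference_performance(calls, lib, "bla_agonist")
  expect_equal(r_ex$n_inconclusive, 1)
  expect_equal(r_ex$tp, length(ref_ago) - 1)
  expect_error(reference_performance(calls, lib, "bla_agonist",
                                     mode = "include_inconclusive"),
               "resolution")
  res <- stats::setNames("active", ref_ago[1])
  r_in <- reference_performance(calls, lib, "bla_agonist",
                                mode = "include_inconclusive",
                                resolution = res)
  expect_equal(r_in$tp, length(ref_ago))
})

test_that("binding concordance applies the logRBA < -3 inactivity rule", {
  comp <- data.frame(
    compound_id = sprintf("C%02d", 1:6),
    logRBA = c(0.5, -3.5, -1, NA, -2.9, -3.01),
    stringsAsFactors = FALSE)
  lib <- structure(list(compounds = comp), class = "screen_library")
  calls <- data.table(
    sample_id = rep(comp$compound_id, 2),
    compound_id = rep(comp$compound_id, 2),
    assay_id = rep(c("bla_agonist", "bla_antagonist"), each = 6),
    outcome = c("active_agonist", "inactive", "inactive", "inactive",
                "inconclusive", "inactive",
                "inactive", "active_antagonist", "inactive", "inactive",
                "inconclusive", "inactive"),
    potency = NA_real_, efficacy = NA_real_)
  r <- binding_concordance(calls, lib, "bla")
  # C01 active+binder: CP; C02 active+logRBA<-3: DP; C03 inactive binder:
  # DN; C05 inconclusive: excluded; C06 logRBA -3.01: binding-inactive CN
  expect_equal(r$cp, 1)
  expect_equal(r$dp, 1)
  expect_equal(r$dn, 1)
  expect_equal(r$cn, 1)
  expect_equal(r$n_inconclusive, 1)
  expect_equal(r$concordance, 0.5)
})

test_that("reproducibility summary percentages and fold changes", {
  rec <- data.table(
    assay_id = "bla_agonist",
    sample_id = sprintf("C%02d", 1:4),
    compound_id = sprintf("C%02d", 1:4),
    category = c("active_match", "active_match", "inactive_match",
                 "mismatch"),
    ac50_fold_change = c(2, 8, NA, NA))
  s <- reproducibility_summary(rec)
  expect_equal(s$active_match, 50)
  expect_equal(s$mismatch, 25)
  expect_equal(s$active_match + s$inactive_match + s$inconclusive +
                 s$mismatch, 100)
  expect_equal(s$ac50_fold_change, 4)  # geometric mean of 2 and 8
})
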