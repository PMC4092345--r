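ca <- function(classes, dirs, mode = "antagonist", platform = "bla",
               viability = NULL, autofluor_max = 0,
               ac50s = rep(1e-6, length(classes)),
               effs = rep(90, length(classes)), noise_sd = 5) {
  call_assay(classes, dirs, ac50s, effs, mode = mode, platform = platform,
             viability = viability, autofluor_max = autofluor_max,
             noise_sd = noise_sd)
}

test_that("clean triplicate activation is an active agonist", {
  r <- ca(c("1.1", "1.1", "1.1"), rep("activation", 3), mode = "agonist")
  expect_equal(r$outcome, "active_agonist")
  expect_equal(r$potency, 1e-6)
  expect_equal(r$efficacy, 90)
})

test_that("three class-4 curves are inactive; no-replicate input errors", {
  r <- ca(c("4", "4", "4"), rep("none", 3))
  expect_equal(r$outcome, "inactive")
  expect_true(is.na(r$potency))
  expect_error(call_assay(character(0), character(0), numeric(0),
                          numeric(0)), "no replicate")
})

test_that("cytotoxicity demotes antagonist candidates within the AC50 window", {
  dirs <- rep("inhibition", 3)
  cls <- rep("1.1", 3)
  # viability AC50 within 3x: demoted
  r <- ca(cls, dirs, viability = list(ac50 = 2e-6, loss_at = 0))
  expect_equal(r$outcome, "inconclusive_antagonist_cytotox")
  # >= 50% viability loss below the antagonist AC50: demoted
  r2 <- ca(cls, dirs, viability = list(ac50 = 9e-5, loss_at = 60))
  expect_equal(r2$outcome, "inconclusive_antagonist_cytotox")
  # distant, shallow viability decline: stays active
  r3 <- ca(cls, dirs, viability = list(ac50 = 9e-5, loss_at = 10))
  expect_equal(r3$outcome, "active_antagonist")
  # clean viability: active
  r4 <- ca(cls, dirs)
  expect_equal(r4$outcome, "active_antagonist")
  # agonist-mode assays have no cytotox demotion path
  r5 <- ca(cls, dirs, mode = "agonist",
           viability = list(ac50 = 2e-6, loss_at = 80))
  expect_equal(r5$outcome, "active_antagonist")
})

test_that("autofluorescence demotes bla agonist candidates only", {
  cls <- rep("1.1", 3); dirs <- rep("activation", 3)
  r <- ca(cls, dirs, mode = "agonist", platform = "bla",
          autofluor_max = 40)
  expect_equal(r$outcome, "inconclusive_agonist_autofluor")
  r2 <- ca(cls, dirs, mode = "agonist", platform = "luc",
           autofluor_max = 40)
  expect_equal(r2$outcome, "active_agonist")
  # sub-threshold fluorescence does not demote
  r3 <- ca(cls, dirs, mode = "agonist", platform = "bla",
           autofluor_max = 10)
  expect_equal(r3$outcome, "active_agonist")
})

test_that("activation in antagonist mode carries agonist labels", {
  cls <- rep("1.1", 3); dirs <- rep("activation", 3)
  r <- ca(cls, dirs, mode = "antagonist", platform = "luc")
  expect_equal(r$outcome, "active_agonist")
  # with concurrent cytotoxicity it is demoted to the agonist cytotox label
  r2 <- ca(cls, dirs, mode = "antagonist", platform = "luc",
           viability = list(ac50 = 1e-6, loss_at = 80))
  expect_equal(r2$outcome, "inconclusive_agonist_cytotox")
})

test_that("weak curves and replicate disagreement are direction-specific inconclusives", {
  r <- ca(c("2.2", "3", "4"), c("inhibition", "inhibition", "none"))
  expect_equal(r$outcome, "inconclusive_antagonist_curve")
  r2 <- ca(c("2.2", "2.2", "4"), c("activation", "activation", "none"),
           mode = "agonist")
  expect_equal(r2$outcome, "inconclusive_agonist_curve")
  # one conclusive active vs two class-4
  r3 <- ca(c("1.1", "4", "4"), c("activation", "none", "none"),
           mode = "agonist")
  expect_equal(r3$outcome, "inconclusive_agonist_curve")
  # opposite conclusive directions
  r4 <- ca(c("1.1", "1.1", "4"),
           c("activation", "inhibition", "none"))
  expect_equal(r4$outcome, "inconclusive")
  # weak responses in both directions
  r5 <- ca(c("2.2", "2.2", "4"), c("activation", "inhibition", "none"))
  expect_equal(r5$outcome, "inconclusive")
})

test_that("decision tree is total, single-valued and never promoted by counter-screens", {
  classes <- c("1.1", "1.2", "2.1", "2.2", "3", "4")
  outcomes <- c("active_agonist", "inconclusive_agonist_curve",
                "inconclusive_agonist_autofluor",
                "inconclusive_agonist_cytotox", "active_antagonist",
                "inconclusive_antagonist_curve",
                "inconclusive_antagonist_cytotox", "inconclusive",
                "inactive")
  actives <- c("active_agonist", "active_antagonist")
  viab_states <- list(NULL, list(ac50 = 2e-6, loss_at = 80),
                      list(ac50 = 9e-5, loss_at = 5))
  af_states <- c(0, 60)
  combos <- expand.grid(c1 = classes, c2 = classes, c3 = classes,
                        d1 = c("activation", "inhibition"),
                        d2 = c("activation", "inhibition"),
                        d3 = c("activation", "inhibition"),
                        stringsAsFactors = FALSE)
  set.seed(1)
  combos <- combos[sample(nrow(combos), 300), ]  # random subsample; order
                                                 # must not matter
  bad_total <- 0L; bad_promote <- 0L
  for (i in seq_len(nrow(combos))) {
    cl <- unlist(combos[i, 1:3], use.names = FALSE)
    di <- unlist(combos[i, 4:6], use.names = FALSE)
    di[cl == "4"] <- "none"
    base <- ca(cl, di)
    if (!(base$outcome %in% outcomes) || length(base$outcome) != 1)
      bad_total <- bad_total + 1L
    for (v in viab_states) for (af in af_states) {
      r <- ca(cl, di, viability = v, autofluor_max = af)
      if (!(r$outcome %in% outcomes)) bad_total <- bad_total + 1L
      if (!(base$outcome %in% actives) && r$outcome %in% actives)
        bad_promote <- bad_promote + 1L
    }
  }
  expect_equal(bad_total, 0L)
  expect_equal(bad_promote, 0L)
})

test_that("replicate reconciliation categories and fold changes", {
  r <- reconcile_replicates(rep("1.1", 3), rep("activation", 3),
                            rep(2e-7, 3))
  expect_equal(r$category, "active_match")
  expect_equal(r$ac50_fold_change, 1)
  r2 <- reconcile_replicates(rep("4", 3), rep("none", 3), rep(NA_real_, 3))
  expect_equal(r2$category, "inactive_match")
  r3 <- reconcile_replicates(c("1.1", "4", "4"),
                             c("activation", "none", "none"),
                             c(1e-7, NA, NA))
  expect_equal(r3$category, "mismatch")
  r4 <- reconcile_replicates(c("2.1", "4", "4"),
                             c("inhibition", "none", "none"),
                             c(1e-7, NA, NA))
  expect_equal(r4$category, "inconclusive")
  r5 <- reconcile_replicates(c("2.1", "2.1", "4"),
                             c("inhibition", "inhibition", "none"),
                             c(1e-7, 4e-7, NA))
  expect_equal(r5$category, "active_match")
  expect_equal(r5$ac50_fold_change, 4)
  # conclusive actives in opposite directions
  r6 <- reconcile_replicates(c("1.1", "1.1"),
                             c("activation", "inhibition"), c(1e-7, 1e-7))
  expect_equal(r6$category, "mismatch")
  expect_error(reconcile_replicates("1.1", "activation", 1e-7),
               "at least 2")
})

test_that("zero-noise duplicates all match and mirror each other's potency", {
  cfg <- small_config(n = 60, seed = 13)
  lib <- generate_library(cfg)
  raw <- assemble_runs(lib, cfg, noise = FALSE)
  norm <- normalize_screen(raw)
  fits <- fit_screen(norm, cfg)
  calls <- call_screen(fits, norm, cfg)
  dc <- duplicate_concordance(calls, lib)
  expect_equal(dc$pairs[, sum(category == "mismatch")], 0)
  am <- dc$pairs[category == "active_match"]
  if (nrow(am) > 0)
    expect_true(all(abs(log10(am$potency_a / am$potency_b)) < 0.01))
  s <- dc$summary
  expect_equal(s$active_match + s$inactive_match + s$inconclusive +
                 s$mismatch, rep(100, nrow(s)))
})

test_that("outcome distribution percentages sum to 100 per assay", {
  calls <- data.table(
    sample_id = rep(sprintf("C%02d", 1:10), 2),
    compound_id = rep(sprintf("C%02d", 1:10), 2),
    assay_id = rep(c("bla_agonist", "luc_agonist"), each = 10),
    outcome = rep(c("inactive", "active_agonist"), 10),
    potency = NA_real_, efficacy = NA_real_)
  d <- outcome_distribution(calls)
  expect_equal(d[, sum(percent), by = assay_id]$V1, c(100, 100),
               tolerance = 1e-9)
  calls[, outcome := "inactive"]
  d2 <- outcome_distribution(calls)
  expect_equal(d2$percent, c(100, 100))
})
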