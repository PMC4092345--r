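#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric two-sided p-value: the sum of the probabilities of
#' all tables with the observed margins whose point probability does not
#' exceed that of the observed table. A table with an empty margin returns
#' p = 1 by convention (flagged with attribute `degenerate`).
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise:
#'   `[[a, b], [c, d]]`.
#' @return two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(counts) == 0)
    stop("empty table", call. = FALSE)
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(structure(1, degenerate = TRUE))
  stats::fisher.test(m)$p.value
}

#' Confusion-matrix performance metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total` and the two-sided Fisher exact p of `[[TP,FP],[FN,TN]]`.
#'
#' @param tp,fp,tn,fn confusion counts.
#' @return list with `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`,
#'   `accuracy`, `fisher_p`.
#' @export
performance_from_counts <- function(tp, fp, tn, fn) {
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       accuracy = (tp + tn) / total,
       fisher_p = fisher_exact_2x2(tp, fp, fn, tn))
}

reference_active_labels <- c("strong", "strong_moderate", "moderate",
                             "weak", "very_weak")

#' Score assay calls against the reference-chemical panel
#'
#' Cross-tabulates active calls against the expected activity of the
#' embedded reference panel. Agonist-mode endpoints treat the agonist
#' reference classes (strong through very-weak) as expected positives and
#' the negatives as expected negatives (the reference antagonists are
#' excluded from the agonist-mode positive class); antagonist-mode
#' endpoints use only the reference antagonists as positives plus the
#' negatives. In the default `exclude_inconclusive` mode, reference
#' compounds with inconclusive calls are dropped from the counts; in
#' `include_inconclusive` mode they are resolved by a caller-supplied
#' override table (mirroring manual review) and counted.
#'
#' @param calls a [call_screen()] result.
#' @param library the [generate_library()] result carrying
#'   `reference_label`.
#' @param assay one of the four reporter endpoints.
#' @param mode `"exclude_inconclusive"` or `"include_inconclusive"`.
#' @param resolution named character vector (compound_id -> forced
#'   `"active"`/`"inactive"`) required for `include_inconclusive`.
#' @return list with the confusion counts and metrics (see
#'   [performance_from_counts()]) plus `n_inconclusive` and the evaluated
#'   compound table.
#' @export
reference_performance <- function(calls, library, assay,
                                  mode = c("exclude_inconclusive",
                                           "include_inconclusive"),
                                  resolution = NULL) {
  mode <- match.arg(mode)
  comp <- library$compounds
  is_ant <- grepl("antagonist", assay)
  if (is_ant) {
    ref <- comp[comp$reference_label %in% c("moderate_antagonist",
                                            "negative"), ]
    expected <- ifelse(ref$reference_label == "moderate_antagonist",
                       "active", "inactive")
    active_outcome <- "active_antagonist"
  } else {
    ref <- comp[comp$reference_label %in% c(reference_active_labels,
                                            "negative"), ]
    expected <- ifelse(ref$reference_label == "negative", "inactive",
                       "active")
    active_outcome <- "active_agonist"
  }
  cc <- calls[assay_id == assay & sample_id == compound_id]
  idx <- match(ref$compound_id, cc$sample_id)
  outcome <- cc$outcome[idx]
  missing <- ref$compound_id[is.na(idx)]
  keep <- !is.na(outcome)
  ref <- ref[keep, ]; expected <- expected[keep]; outcome <- outcome[keep]

  called <- ifelse(outcome == active_outcome, "active",
                   ifelse(outcome == "inactive", "inactive",
                          "inconclusive"))
  n_inc <- sum(called == "inconclusive")
  if (mode == "exclude_inconclusive") {
    keep <- called != "inconclusive"
  } else {
    if (n_inc > 0) {
      if (is.null(resolution))
        stop("include_inconclusive mode needs a resolution table",
             call. = FALSE)
      unres <- setdiff(ref$compound_id[called == "inconclusive"],
                       names(resolution))
      if (length(unres) > 0)
        stop("unresolved inconclusive compounds: ",
             paste(unres, collapse = ", "), call. = FALSE)
      called[called == "inconclusive"] <-
        resolution[ref$compound_id[called == "inconclusive"]]
    }
    keep <- rep(TRUE, length(called))
  }
  e <- expected[keep]; k <- called[keep]
  tp <- sum(k == "active" & e == "active")
  fp <- sum(k == "active" & e == "inactive")
  tn <- sum(k == "inactive" & e == "inactive")
  fn <- sum(k == "inactive" & e == "active")
  out <- performance_from_counts(tp, fp, tn, fn)
  out$n_inconclusive <- n_inc
  out$missing <- missing
  out$evaluated <- data.frame(compound_id = ref$compound_id[keep],
                              expected = e, called = k,
                              stringsAsFactors = FALSE)
  out
}

#' Concordance counts and metrics
#'
#' @param cp,dp,cn,dn concordant/discordant positive/negative counts.
#' @param n_inconclusive number of compounds excluded as inconclusive.
#' @return list with the counts, `concordance = (CP+CN)/(CP+DP+CN+DN)` and
#'   the two-sided Fisher exact p of `[[CP,DP],[DN,CN]]`.
#' @export
concordance_from_counts <- function(cp, dp, cn, dn, n_inconclusive = 0) {
  total <- cp + dp + cn + dn
  if (total == 0) stop("no concordance counts", call. = FALSE)
  list(cp = cp, dp = dp, cn = cn, dn = dn,
       n_inconclusive = n_inconclusive,
       concordance = (cp + cn) / total,
       fisher_p = fisher_exact_2x2(cp, dp, dn, cn))
}

#' Concordance of functional calls with binding-assay labels
#'
#' Per reporter platform, a compound is functionally "active" when it is an
#' active agonist or active antagonist in either screening mode of that
#' platform, and binding-active when its log relative binding affinity is
#' at least -3 (binding weaker than 1/1000 of the endogenous agonist counts
#' as binding-inactive). Compounds with only inconclusive functional calls
#' are excluded and counted; compounds without a binding label are skipped.
#'
#' @param calls a [call_screen()] result.
#' @param library the [generate_library()] result carrying `logRBA`.
#' @param platform `"bla"` or `"luc"`.
#' @return a [concordance_from_counts()] result.
#' @export
binding_concordance <- function(calls, library, platform = c("bla", "luc")) {
  platform <- match.arg(platform)
  comp <- library$compounds
  comp <- comp[!is.na(comp$logRBA), ]
  assays <- paste0(platform, c("_agonist", "_antagonist"))
  cc <- calls[assay_id %in% assays & sample_id == compound_id &
                compound_id %in% comp$compound_id]
  per <- cc[, .(
    func = if (any(outcome %in% c("active_agonist", "active_antagonist")))
      "active"
    else if (all(outcome == "inactive")) "inactive"
    else "inconclusive"), by = compound_id]
  per[, bind := ifelse(
    comp$logRBA[match(compound_id, comp$compound_id)] >= -3,
    "active", "inactive")]
  n_inc <- sum(per$func == "inconclusive")
  per <- per[func != "inconclusive"]
  concordance_from_counts(
    cp = per[, sum(func == "active" & bind == "active")],
    dp = per[, sum(func == "active" & bind == "inactive")],
    cn = per[, sum(func == "inactive" & bind == "inactive")],
    dn = per[, sum(func == "inactive" & bind == "active")],
    n_inconclusive = n_inc)
}

#' Summarise replicate reproducibility per assay
#'
#' Category percentages (active match, inactive match, inconclusive,
#' mismatch) and the geometric mean AC50 fold change over active matches,
#' per assay.
#'
#' @param reconciled a [reconcile_screen()] result.
#' @return `data.table`, one row per assay.
#' @export
reproducibility_summary <- function(reconciled) {
  reconciled[, {
    fc <- ac50_fold_change[category == "active_match" &
                             !is.na(ac50_fold_change)]
    .(active_match = 100 * mean(category == "active_match"),
      inactive_match = 100 * mean(category == "inactive_match"),
      inconclusive = 100 * mean(category == "inconclusive"),
      mismatch = 100 * mean(category == "mismatch"),
      ac50_fold_change = if (length(fc) > 0) exp(mean(log(fc)))
      else NA_real_)
  }, by = assay_id]
}

#' Report-scale rounding
#'
#' Percentages to whole percent and p-values to two significant figures,
#' the precision used in screening summary tables.
#'
#' @param x proportion in `[0, 1]`.
#' @param p p-value.
#' @return numeric scalar.
#' @export
as_report_percent <- function(x) round(100 * x)

#' @rdname as_report_percent
#' @export
as_report_p <- function(p) signif(p, 2)
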