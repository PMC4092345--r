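conclusive_active_classes <- c("1.1", "1.2", "2.1")
weak_classes <- c("2.2", "3")

#' Assign an activity outcome from triplicate curves and counter-screens
#'
#' The per-assay decision tree integrating the three replicate curve grades
#' with the cytotoxicity and autofluorescence counter-screens:
#' \enumerate{
#'   \item a majority (>= 2/3) of class-4 curves with no conclusively active
#'     replicate is \emph{inactive};
#'   \item a majority of conclusively active curves (classes 1.1/1.2/2.1) in
#'     one direction is a candidate active in that direction;
#'   \item a candidate antagonist is demoted to
#'     \emph{inconclusive_antagonist_cytotox} when the viability readout
#'     declines with an AC50 within `cytotox_window`-fold of the antagonist
#'     AC50, or loses >= 50\% viability at or below it;
#'   \item a candidate agonist read in a fluorescence channel (bla platform)
#'     is demoted to \emph{inconclusive_agonist_autofluor} when the
#'     compound's autofluorescence in the detection channels exceeds
#'     `3 * noise_sd` at active concentrations; in antagonist-mode assays a
#'     candidate agonist with concurrent viability loss is demoted to
#'     \emph{inconclusive_agonist_cytotox};
#'   \item a majority of weak curves (classes 2.2/3), or disagreement
#'     between an active replicate and class-4 replicates, is the
#'     direction's poor-curve-quality inconclusive;
#'   \item conclusively active replicates in opposite directions are
#'     \emph{inconclusive};
#'   \item activation observed in an antagonist-mode assay carries agonist
#'     labels.
#' }
#' Demotions only ever move a candidate active to an inconclusive category.
#'
#' @param curve_classes character vector of replicate curve classes
#'   (from [classify_curve()]).
#' @param directions replicate fit directions (`"activation"`,
#'   `"inhibition"`, `"none"`).
#' @param ac50s,efficacies replicate fitted AC50s (molar) and efficacies.
#' @param mode `"agonist"` or `"antagonist"` (the assay's screening mode).
#' @param platform `"bla"` (fluorescence readout, autofluorescence-checked)
#'   or `"luc"` (luminescence readout).
#' @param viability `NULL`, or a list with `ac50` (molar AC50 of the
#'   matched viability decline, `NA` if none) and `loss_at` (percent
#'   viability loss at the candidate AC50).
#' @param autofluor_max maximal autofluorescence response (percent) of the
#'   compound in the assay's detection channels at active concentrations.
#' @param noise_sd assay noise on the percent scale.
#' @param cytotox_window AC50 ratio defining cytotoxicity overlap.
#' @return list with `outcome` (one of the nine activity-outcome
#'   categories), `potency` (median AC50 over conclusive active replicates,
#'   `NA` unless a candidate was formed) and `efficacy` (median efficacy).
#' @export
call_assay <- function(curve_classes, directions, ac50s, efficacies,
                       mode = c("agonist", "antagonist"),
                       platform = c("bla", "luc"),
                       viability = NULL, autofluor_max = 0, noise_sd = 5,
                       cytotox_window = 3) {
  mode <- match.arg(mode); platform <- match.arg(platform)
  if (length(curve_classes) == 0)
    stop("no replicate curves supplied", call. = FALSE)
  act <- curve_classes %in% conclusive_active_classes
  n_up <- sum(act & directions == "activation")
  n_dn <- sum(act & directions == "inhibition")
  n4 <- sum(curve_classes == "4")

  summ <- function(dir) {
    sel <- act & directions == dir
    list(potency = stats::median(ac50s[sel]),
         efficacy = stats::median(efficacies[sel]))
  }
  res <- function(outcome, dir = NULL) {
    s <- if (is.null(dir)) list(potency = NA_real_, efficacy = NA_real_)
         else summ(dir)
    list(outcome = outcome, potency = s$potency, efficacy = s$efficacy)
  }

  # (1) majority inactive
  if (n4 >= 2 && n_up + n_dn == 0) return(res("inactive"))
  # (6) conclusive actives in both directions
  if (n_up >= 1 && n_dn >= 1) return(res("inconclusive"))

  cyto_overlap <- function(cand_ac50) {
    if (is.null(viability) || is.na(cand_ac50)) return(FALSE)
    hit <- FALSE
    if (!is.null(viability$ac50) && !is.na(viability$ac50)) {
      ratio <- max(viability$ac50, cand_ac50) /
        min(viability$ac50, cand_ac50)
      hit <- ratio <= cytotox_window
    }
    if (!hit && !is.null(viability$loss_at) && !is.na(viability$loss_at))
      hit <- viability$loss_at >= 50
    hit
  }

  # (2) candidate active, activation direction ((7): agonist labels in
  # antagonist mode)
  if (n_up >= 2) {
    s <- summ("activation")
    if (platform == "bla" && autofluor_max > 3 * noise_sd)
      return(list(outcome = "inconclusive_agonist_autofluor",
                  potency = s$potency, efficacy = s$efficacy))
    if (mode == "antagonist" && cyto_overlap(s$potency))
      return(list(outcome = "inconclusive_agonist_cytotox",
                  potency = s$potency, efficacy = s$efficacy))
    return(list(outcome = "active_agonist", potency = s$potency,
                efficacy = s$efficacy))
  }
  # (2)/(3) candidate active, inhibition direction
  if (n_dn >= 2) {
    s <- summ("inhibition")
    if (mode == "antagonist" && cyto_overlap(s$potency))
      return(list(outcome = "inconclusive_antagonist_cytotox",
                  potency = s$potency, efficacy = s$efficacy))
    return(list(outcome = "active_antagonist", potency = s$potency,
                efficacy = s$efficacy))
  }

  # (5) weak curves / replicate disagreement: poor-curve inconclusive in
  # the direction of the responding replicates
  resp_dirs <- unique(directions[curve_classes != "4" &
                                   directions != "none"])
  if (length(resp_dirs) == 1) {
    if (resp_dirs == "activation")
      return(res("inconclusive_agonist_curve"))
    return(res("inconclusive_antagonist_curve"))
  }
  res("inconclusive")
}

viability_assay_for <- c(bla_agonist = NA_character_,
                         bla_antagonist = "bla_viability",
                         luc_agonist = NA_character_,
                         luc_antagonist = "luc_viability")

#' Call activity outcomes for every sample of a screen
#'
#' Applies [call_assay()] to the four reporter endpoints of every sample,
#' wiring in the matched viability curves (antagonist-mode assays are
#' multiplexed with viability on the same platform) and the
#' autofluorescence profile (bla assays are checked against the blue and
#' green channels; the luminescent luc readout is not
#' autofluorescence-demoted).
#'
#' @param fits a [fit_screen()] result.
#' @param normalized the matching [normalize_screen()] result (source of
#'   the autofluorescence profile).
#' @param config the [screen_config()].
#' @return `data.table` of class `screen_calls`: `sample_id`,
#'   `compound_id`, `assay_id`, `outcome`, `potency`, `efficacy`.
#' @export
call_screen <- function(fits, normalized, config) {
  noise_sd <- attr(fits, "noise_sd")
  af <- autofluor_profile(normalized)
  af_bg <- af[channel %in% c("blue", "green")]

  er_assays <- c("bla_agonist", "bla_antagonist", "luc_agonist",
                 "luc_antagonist")
  viab <- fits[assay_id %in% c("bla_viability", "luc_viability")]
  viab_summ <- viab[direction == "inhibition" & converged == TRUE,
                    .(v_ac50 = stats::median(ac50),
                      v_hill = stats::median(hill),
                      v_top = stats::median(top),
                      v_bottom = stats::median(bottom)),
                    by = .(sample_id, assay_id)]

  af_max_all <- af_bg[, .(af_max = max(activity),
                          af_conc_max = concentration_M[which.max(activity)]),
                      by = sample_id]

  out <- vector("list", length(er_assays))
  for (i in seq_along(er_assays)) {
    aid <- er_assays[i]
    mode <- if (grepl("antagonist", aid)) "antagonist" else "agonist"
    platform <- if (grepl("^bla", aid)) "bla" else "luc"
    va <- viability_assay_for[[aid]]
    sub <- fits[assay_id == aid]
    if (!is.na(va)) {
      sub <- merge(sub, viab_summ[assay_id == va,
                                  .(sample_id, v_ac50, v_hill, v_top,
                                    v_bottom)],
                   by = "sample_id", all.x = TRUE)
    } else {
      sub[, c("v_ac50", "v_hill", "v_top", "v_bottom") :=
            .(NA_real_, NA_real_, NA_real_, NA_real_)]
    }
    sub <- merge(sub, af_max_all, by = "sample_id", all.x = TRUE)
    calls <- sub[, {
      viability <- NULL
      if (!is.na(v_ac50[1])) {
        cand <- stats::median(ac50[curve_class %in%
                                     conclusive_active_classes],
                              na.rm = TRUE)
        loss <- if (is.na(cand)) NA_real_ else
          abs(hill_response(cand, v_ac50[1], v_hill[1], v_top[1],
                            v_bottom[1]))
        viability <- list(ac50 = v_ac50[1], loss_at = loss)
      }
      afm <- 0
      if (platform == "bla" && !is.na(af_max[1])) afm <- af_max[1]
      cl <- call_assay(curve_class, direction, ac50, efficacy,
                       mode = mode, platform = platform,
                       viability = viability, autofluor_max = afm,
                       noise_sd = noise_sd[[aid]],
                       cytotox_window = config$cytotox_window)
      .(outcome = cl$outcome, potency = cl$potency,
        efficacy_pct = cl$efficacy)
    }, by = .(sample_id, compound_id)]
    calls[, assay_id := aid]
    out[[i]] <- calls
  }
  calls <- data.table::rbindlist(out)
  data.table::setnames(calls, "efficacy_pct", "efficacy")
  data.table::setcolorder(calls, c("sample_id", "compound_id", "assay_id",
                                   "outcome", "potency", "efficacy"))
  data.table::setattr(calls, "class", c("screen_calls", class(calls)))
  calls[]
}

#' Reconcile replicate curves into a reproducibility category
#'
#' Classifies a set of replicate titrations of the same sample into
#' \emph{active_match} (>= 2 conclusively active curves in the same
#' direction, no high-quality conflict), \emph{inactive_match} (>= 2
#' class-4 curves, no conclusively active curve), \emph{mismatch}
#' (a high-quality active curve, class 1.1/1.2, co-occurring with a class-4
#' curve, or conclusive actives in opposite directions), or
#' \emph{inconclusive} otherwise. For active matches the AC50 fold change
#' `max/min` across the matched replicates is reported.
#'
#' @param curve_classes,directions,ac50s replicate curve grades, directions
#'   and fitted AC50s (>= 2 replicates).
#' @return list with `category` and `ac50_fold_change` (`NA` unless
#'   active_match).
#' @export
reconcile_replicates <- function(curve_classes, directions, ac50s) {
  if (length(curve_classes) < 2)
    stop("need at least 2 replicate calls", call. = FALSE)
  act <- curve_classes %in% conclusive_active_classes
  hq_act <- any(curve_classes %in% c("1.1", "1.2"))
  n_up <- sum(act & directions == "activation")
  n_dn <- sum(act & directions == "inhibition")
  n4 <- sum(curve_classes == "4")
  opposite <- n_up >= 1 && n_dn >= 1
  conflict <- (hq_act && n4 >= 1) || opposite
  if ((n_up >= 2 || n_dn >= 2) && !conflict) {
    sel <- act & directions ==
      (if (n_up >= 2) "activation" else "inhibition")
    a <- ac50s[sel & !is.na(ac50s)]
    fold <- if (length(a) >= 2) max(a) / min(a) else 1
    return(list(category = "active_match", ac50_fold_change = fold))
  }
  if (n4 >= 2 && n_up + n_dn == 0)
    return(list(category = "inactive_match", ac50_fold_change = NA_real_))
  if (conflict)
    return(list(category = "mismatch", ac50_fold_change = NA_real_))
  list(category = "inconclusive", ac50_fold_change = NA_real_)
}

#' Reconcile every sample's triplicate runs
#'
#' @param fits a [fit_screen()] result.
#' @return `data.table`: `sample_id`, `compound_id`, `assay_id`,
#'   `category`, `ac50_fold_change`.
#' @export
reconcile_screen <- function(fits) {
  fits[, {
    r <- reconcile_replicates(curve_class, direction, ac50)
    .(category = r$category, ac50_fold_change = r$ac50_fold_change)
  }, by = .(assay_id, sample_id, compound_id)]
}

#' Concordance of the intra-plate duplicate controls
#'
#' Pairs the two copies of every duplicate-control compound and classifies
#' the pair per assay: \emph{active_match} when both copies are called
#' active in the same direction, \emph{inactive_match} when both are
#' inactive, \emph{mismatch} for active vs inactive (or opposite
#' directions), \emph{inconclusive} when either copy is inconclusive. For
#' active-matched pairs the squared Pearson correlation of log10 AC50
#' between copies is reported per assay.
#'
#' @param calls a [call_screen()] result.
#' @param library the [generate_library()] result (source of duplicate
#'   flags).
#' @return list with `pairs` (per compound x assay categories) and
#'   `summary` (per assay: category percentages, number of active pairs and
#'   `r2` of log10 AC50).
#' @export
duplicate_concordance <- function(calls, library) {
  dup_ids <- library$compounds$compound_id[
    library$compounds$is_duplicate_control]
  a <- calls[compound_id %in% dup_ids & sample_id == compound_id,
             .(compound_id, assay_id, outcome_a = outcome,
               potency_a = potency)]
  b <- calls[compound_id %in% dup_ids & sample_id != compound_id,
             .(compound_id, assay_id, outcome_b = outcome,
               potency_b = potency)]
  pairs <- merge(a, b, by = c("compound_id", "assay_id"))
  cat_pair <- function(oa, ob) {
    active <- c("active_agonist", "active_antagonist")
    if (oa %in% active && ob %in% active) {
      if (oa == ob) "active_match" else "mismatch"
    } else if (oa == "inactive" && ob == "inactive") {
      "inactive_match"
    } else if ((oa %in% active && ob == "inactive") ||
               (ob %in% active && oa == "inactive")) {
      "mismatch"
    } else "inconclusive"
  }
  pairs[, category := mapply(cat_pair, outcome_a, outcome_b)]
  summary <- pairs[, {
    am <- category == "active_match" & !is.na(potency_a) & !is.na(potency_b)
    r2 <- if (sum(am) >= 3)
      stats::cor(log10(potency_a[am]), log10(potency_b[am]))^2
    else NA_real_
    .(active_match = 100 * mean(category == "active_match"),
      inactive_match = 100 * mean(category == "inactive_match"),
      inconclusive = 100 * mean(category == "inconclusive"),
      mismatch = 100 * mean(category == "mismatch"),
      n_active_pairs = sum(am), r2_log_ac50 = r2)
  }, by = assay_id]
  list(pairs = pairs[], summary = summary[])
}

#' Distribution of activity outcomes
#'
#' Percentage of samples in each activity-outcome category, per assay;
#' percentages sum to 100 within an assay.
#'
#' @param calls a [call_screen()] result.
#' @return `data.table`: `assay_id`, `outcome`, `n`, `percent`.
#' @export
outcome_distribution <- function(calls) {
  d <- calls[, .(n = .N), by = .(assay_id, outcome)]
  d[, percent := 100 * n / sum(n), by = assay_id]
  data.table::setorder(d, assay_id, -percent)
  d[]
}
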