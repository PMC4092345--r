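#' Generate a synthetic compound library with ground-truth pharmacology
#'
#' Draws a compound library whose members carry known receptor pharmacology
#' (truth class, per-platform potency and efficacy), counter-screen
#' liabilities (cytotoxicity, autofluorescence), binding-affinity labels
#' (logRBA relative to the endogenous full agonist), reference-panel labels,
#' binary structural fingerprints organised into families, and duplicate
#' control flags. Everything downstream of the generator can therefore be
#' scored against truth.
#'
#' Truth classes behave as follows in the reporter assays:
#' \describe{
#'   \item{full_agonist}{activates both platforms at 80-120\% efficacy.}
#'   \item{partial_agonist}{activates at 15-60\% efficacy; in antagonist
#'     mode it displaces the stimulating full agonist and appears as a
#'     partial inhibitor.}
#'   \item{antagonist}{inhibits the stimulated signal fully; silent in
#'     agonist mode.}
#'   \item{cytotoxic_only}{no receptor activity; kills cells at high
#'     concentration, depressing the antagonist-mode and viability readouts
#'     with a shared AC50.}
#'   \item{autofluorescent}{no receptor activity; adds a
#'     concentration-proportional fluorescence offset in its flagged
#'     channels, contaminating the fluorescence-read (bla) assays.}
#'   \item{selective_modulator}{agonist on one platform and antagonist on
#'     the other (direction randomised per compound).}
#'   \item{inactive}{nothing.}
#' }
#'
#' A reference panel mirroring a 39-chemical expert-curated set is embedded:
#' 3 strong, 1 strong-moderate, 5 moderate and 15 weak agonists, 4 very-weak
#' agonists, 6 moderate antagonists and 5 negatives, assigned consistently
#' with the drawn potencies. Two structural families are planted
#' deterministically for enrichment validation: one of full agonists and one
#' mixing antagonists with cytotoxic compounds (the classic
#' cytotoxicity-confounded antagonist cluster).
#'
#' @param config a [screen_config()].
#' @return object of class `screen_library`: list with `compounds`
#'   (data.frame, one row per compound) and `fingerprints` (0/1 matrix,
#'   one row per compound).
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  withr::with_seed(derive_seed(config$seed, 1L), {
    n <- config$n_compounds
    classes <- names(config$mixture)
    truth <- sample(classes, n, replace = TRUE, prob = config$mixture)
    id <- sprintf("C%05d", seq_len(n))

    # receptor potency: shared log10 AC50 with small per-platform offsets
    log_ac50 <- stats::runif(n, -8.5, -5.5)
    ac50_bla <- 10^(log_ac50 + stats::rnorm(n, 0, 0.15))
    ac50_luc <- 10^(log_ac50 + stats::rnorm(n, 0, 0.15))

    eff <- numeric(n)
    eff[truth == "full_agonist"]    <- stats::runif(sum(truth == "full_agonist"), 80, 120)
    eff[truth == "partial_agonist"] <- stats::runif(sum(truth == "partial_agonist"), 15, 60)
    eff[truth == "antagonist"]      <- 0
    eff[truth == "selective_modulator"] <-
      stats::runif(sum(truth == "selective_modulator"), 30, 70)

    dir_bla <- rep("none", n); dir_luc <- rep("none", n)
    ago <- truth %in% c("full_agonist", "partial_agonist")
    dir_bla[ago] <- "agonist"; dir_luc[ago] <- "agonist"
    ant <- truth == "antagonist"
    dir_bla[ant] <- "antagonist"; dir_luc[ant] <- "antagonist"
    sel <- which(truth == "selective_modulator")
    flip <- stats::runif(length(sel)) < 0.5
    dir_luc[sel] <- ifelse(flip, "agonist", "antagonist")
    dir_bla[sel] <- ifelse(flip, "antagonist", "agonist")

    er_active <- dir_bla != "none" | dir_luc != "none"
    ac50_bla[dir_bla == "none"] <- NA_real_
    ac50_luc[dir_luc == "none"] <- NA_real_

    cytotox_ac50 <- rep(NA_real_, n)
    cyt <- truth == "cytotoxic_only"
    cytotox_ac50[cyt] <- 10^stats::runif(sum(cyt), -5.8, -4.6)

    autofluor_channels <- rep("", n)
    autofluor_amp <- rep(0, n)
    auto <- which(truth == "autofluorescent")
    for (i in auto) {
      k <- sample(1:2, 1)
      autofluor_channels[i] <- paste(sample(c("blue", "green", "red"), k),
                                     collapse = ";")
    }
    autofluor_amp[auto] <- stats::runif(length(auto), 150, 400)

    # binding affinity vs the endogenous full agonist (AC50 ~ 3e-10 M)
    logRBA <- rep(NA_real_, n)
    pot <- ifelse(is.na(ac50_bla), ac50_luc,
                  ifelse(is.na(ac50_luc), ac50_bla,
                         sqrt(ac50_bla * ac50_luc)))
    logRBA[er_active] <- log10(3e-10 / pot[er_active]) +
      stats::rnorm(sum(er_active), 0, 0.4)
    nonbinder <- which(!er_active)
    pick <- nonbinder[stats::runif(length(nonbinder)) < 0.3]
    logRBA[pick] <- stats::runif(length(pick), -5, -3.2)

    reference_label <- rep("none", n)
    assign_ref <- function(pool, k, label) {
      k <- min(k, length(pool))
      if (k > 0) reference_label[pool[seq_len(k)]] <<- label
      if (k > 0) pool[-seq_len(k)] else pool
    }
    ago_pool <- which(truth == "full_agonist")
    ago_pool <- ago_pool[order(pot[ago_pool])]       # most potent first
    ago_pool <- assign_ref(ago_pool, 3, "strong")
    ago_pool <- assign_ref(ago_pool, 1, "strong_moderate")
    ago_pool <- assign_ref(ago_pool, 5, "moderate")
    par_pool <- which(truth == "partial_agonist")
    par_pool <- par_pool[order(pot[par_pool])]
    par_pool <- assign_ref(par_pool, 15, "weak")
    par_pool <- assign_ref(rev(par_pool), 4, "very_weak")  # least potent
    ant_pool <- which(truth == "antagonist")
    ant_pool <- assign_ref(ant_pool, 6, "moderate_antagonist")
    neg_pool <- which(truth == "inactive")
    assign_ref(neg_pool, 5, "negative")

    is_dup <- rep(FALSE, n)
    is_dup[sample.int(n, min(config$n_duplicates, n))] <- TRUE

    # structural families: two planted (agonist; antagonist+cytotox mix),
    # remainder partitioned within truth class
    family_id <- integer(n)
    fa <- which(truth == "full_agonist")
    fa <- fa[seq_len(min(config$planted_agonist_family, length(fa)))]
    family_id[fa] <- 1L
    half <- config$planted_confound_family %/% 2
    fc_a <- setdiff(which(truth == "antagonist"), fa)
    fc_c <- which(truth == "cytotoxic_only")
    fc <- c(fc_a[seq_len(min(half, length(fc_a)))],
            fc_c[seq_len(min(config$planted_confound_family - half,
                             length(fc_c)))])
    family_id[fc] <- 2L
    next_fam <- 3L
    for (cl in classes) {
      left <- which(truth == cl & family_id == 0L)
      while (length(left) > 0) {
        sz <- max(1L, stats::rpois(1, config$family_size))
        take <- left[seq_len(min(sz, length(left)))]
        family_id[take] <- next_fam
        next_fam <- next_fam + 1L
        left <- left[-seq_len(min(sz, length(left)))]
      }
    }

    bits <- config$fingerprint_bits
    n_fam <- max(family_id)
    protos <- matrix(stats::rbinom(n_fam * bits, 1, 0.3), nrow = n_fam)
    fp <- protos[family_id, , drop = FALSE]
    flips <- matrix(stats::runif(n * bits) < config$bit_flip_prob, nrow = n)
    fp <- abs(fp - flips * 1L)
    storage.mode(fp) <- "integer"
    rownames(fp) <- id

    compounds <- data.frame(
      compound_id = id, truth_class = truth,
      er_dir_bla = dir_bla, er_dir_luc = dir_luc,
      er_ac50_bla = ac50_bla, er_ac50_luc = ac50_luc,
      er_eff = eff, cytotox_ac50 = cytotox_ac50,
      autofluor_channels = autofluor_channels,
      autofluor_amp = autofluor_amp,
      logRBA = logRBA, reference_label = reference_label,
      family_id = family_id, is_duplicate_control = is_dup,
      stringsAsFactors = FALSE
    )
    structure(list(compounds = compounds, fingerprints = fp),
              class = "screen_library")
  })
}

#' @export
print.screen_library <- function(x, ...) {
  cat(sprintf("screen_library: %d compounds, %d-bit fingerprints\n",
              nrow(x$compounds), ncol(x$fingerprints)))
  print(table(x$compounds$truth_class))
  invisible(x)
}
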