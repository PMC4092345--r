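#' Normalize one plate against its embedded controls
#'
#' Converts raw signals to percent activity using the plate's own controls:
#' 0 is the negative-control level (for antagonist-mode plates the
#' stimulated, uninhibited wells; for viability plates untreated cells) and
#' the magnitude 100 is set by the mean of the positive-control titration
#' wells at its top two concentrations. Activity is signed:
#' `100 * (x - mu_neg) / |mu_top - mu_neg|`, so activation is positive and
#' inhibition (antagonist and viability plates) runs to -100.
#'
#' Plate statistics from the same controls: signal-to-background
#' `S/B = max(mu_top, mu_neg) / min(mu_top, mu_neg)`, percent
#' `CV = 100 * sd_neg / mu_neg`, and
#' `Z' = 1 - 3 (sd_pos + sd_neg) / |mu_top - mu_neg|`. Plates failing the
#' conventional thresholds (S/B > 3, CV < 10, Z' > 0.5) are flagged, not
#' dropped.
#'
#' @param plate rows of a `screen_raw` table belonging to one plate.
#' @return list with `normalized` (the compound and control wells with an
#'   `activity` column) and `stats` (1-row data.frame of plate statistics).
#' @export
normalize_plate <- function(plate) {
  plate <- data.table::as.data.table(plate)
  if (length(unique(plate$plate_id)) != 1)
    stop("normalize_plate expects a single plate", call. = FALSE)
  neg <- plate$signal[plate$role == "neg"]
  pos <- plate[role == "pos"]
  if (length(neg) == 0 || nrow(pos) == 0)
    stop("plate is missing control wells", call. = FALSE)
  top2 <- sort(unique(pos$concentration_M), decreasing = TRUE)[1:2]
  pos_top <- pos$signal[pos$concentration_M %in% top2]
  mu_neg <- mean(neg); mu_top <- mean(pos_top)
  sd_neg <- stats::sd(neg); sd_pos <- stats::sd(pos_top)
  span <- abs(mu_top - mu_neg)
  z_prime <- if (span == 0) NA_real_ else 1 - 3 * (sd_pos + sd_neg) / span
  stats <- data.frame(
    plate_id = plate$plate_id[1], assay_id = plate$assay_id[1],
    run = plate$run[1],
    s_b = max(mu_top, mu_neg) / min(mu_top, mu_neg),
    cv = 100 * sd_neg / mu_neg,
    z_prime = z_prime,
    mu_neg = mu_neg, mu_top = mu_top,
    pass_sb = max(mu_top, mu_neg) / min(mu_top, mu_neg) > 3,
    pass_cv = 100 * sd_neg / mu_neg < 10,
    pass_zprime = !is.na(z_prime) && z_prime > 0.5,
    stringsAsFactors = FALSE)
  out <- data.table::copy(plate)
  if (span == 0) {
    out[, activity := NA_real_]
  } else {
    out[, activity := 100 * (signal - mu_neg) / span]
  }
  list(normalized = out[], stats = stats)
}

#' Normalize a whole screen
#'
#' Applies [normalize_plate()] to every plate of a raw screen.
#'
#' @param raw a `screen_raw` table from [assemble_runs()].
#' @return list of class `screen_normalized`: `normalized` (long table with
#'   `activity`) and `plate_stats` (one row per plate).
#' @export
normalize_screen <- function(raw) {
  raw <- data.table::as.data.table(raw)
  norm <- raw[, {
    neg <- signal[role == "neg"]
    pconc <- concentration_M[role == "pos"]
    psig <- signal[role == "pos"]
    top2 <- sort(unique(pconc), decreasing = TRUE)[1:2]
    mu_neg <- mean(neg); mu_top <- mean(psig[pconc %in% top2])
    span <- abs(mu_top - mu_neg)
    sd_neg <- stats::sd(neg); sd_pos <- stats::sd(psig[pconc %in% top2])
    .(well = well, role = role, sample_id = sample_id,
      compound_id = compound_id, conc_index = conc_index,
      concentration_M = concentration_M,
      activity = if (span == 0) rep(NA_real_, .N) else
        100 * (signal - mu_neg) / span,
      mu_neg = mu_neg, mu_top = mu_top, sd_neg = sd_neg, sd_pos = sd_pos)
  }, by = .(plate_id, assay_id, run)]
  stats <- unique(norm[, .(plate_id, assay_id, run, mu_neg, mu_top,
                           sd_neg, sd_pos)])
  stats[, span := abs(mu_top - mu_neg)]
  stats[, s_b := pmax(mu_top, mu_neg) / pmin(mu_top, mu_neg)]
  stats[, cv := 100 * sd_neg / mu_neg]
  stats[, z_prime := data.table::fifelse(span == 0, NA_real_,
                                         1 - 3 * (sd_pos + sd_neg) / span)]
  stats[, pass_sb := s_b > 3]
  stats[, pass_cv := cv < 10]
  stats[, pass_zprime := !is.na(z_prime) & z_prime > 0.5]
  norm[, c("mu_neg", "mu_top", "sd_neg", "sd_pos") := NULL]
  structure(list(normalized = norm[], plate_stats = stats[]),
            class = "screen_normalized")
}

#' Embedded control-titration AC50s
#'
#' Fits the Hill model to the normalized positive-control titration of every
#' plate and summarises, per assay, the geometric mean AC50 and the
#' geometric standard deviation expressed as a fold factor
#' (`10^sd(log10 AC50)`); a well-behaved screen keeps the fold SD under 3.
#'
#' @param normalized a [normalize_screen()] result.
#' @return list with `per_plate` (plate_id, assay_id, run, ac50, r2,
#'   converged) and `summary` (per assay: geometric mean AC50, `sd_fold`,
#'   number of converged plates).
#' @export
control_titration_ac50 <- function(normalized) {
  norm <- normalized$normalized
  per_plate <- norm[role == "pos",
    {
      f <- fit_hill(concentration_M, activity, allow_mask = FALSE)
      .(ac50 = potency(f), r2 = f$r2, converged = f$converged)
    },
    by = .(plate_id, assay_id, run)]
  summary <- per_plate[converged == TRUE & !is.na(ac50),
    .(ac50_geomean = 10^mean(log10(ac50)),
      sd_fold = 10^stats::sd(log10(ac50)),
      n_plates = .N),
    by = assay_id]
  summary[is.na(sd_fold), sd_fold := 1]  # single plate
  list(per_plate = per_plate[], summary = summary[])
}
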