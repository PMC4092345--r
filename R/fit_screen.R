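#' Fit and classify every titration of a screen
#'
#' Runs [fit_hill()] and [classify_curve()] over every
#' (sample, assay, run) titration of the reporter and viability assays.
#' Titrations whose largest absolute response is below the class-4
#' threshold `max(3 * noise_sd, 20)` are classified inactive without a fit
#' (the classifier would grade them 4 regardless). The per-assay noise level
#' is estimated as the standard deviation of the normalized negative-control
#' activities.
#'
#' @param normalized a [normalize_screen()] result.
#' @param config the [screen_config()] used to build the screen.
#' @return `data.table` of class `screen_fits`, one row per titration:
#'   fitted parameters, `r2`, `converged`, `direction`, `curve_class`,
#'   `efficacy`, `max_resp`, `n_masked`. The per-assay noise estimate is
#'   attached as attribute `noise_sd`.
#' @export
fit_screen <- function(normalized, config) {
  norm <- normalized$normalized
  fit_assays <- setdiff(assay_table()$assay_id,
                        c("autofluor_blue", "autofluor_green",
                          "autofluor_red"))
  noise_tab <- norm[role == "neg" & assay_id %in% fit_assays,
                    .(noise_sd = stats::sd(activity)), by = assay_id]
  noise_sd <- stats::setNames(noise_tab$noise_sd, noise_tab$assay_id)

  dat <- norm[role == "compound" & assay_id %in% fit_assays]
  fits <- dat[, {
    ns <- noise_sd[[.BY$assay_id]]
    thr <- max(3 * ns, 20)
    o <- order(concentration_M)
    conc <- concentration_M[o]; resp <- activity[o]
    mx <- max(abs(resp))
    if (mx < thr) {
      .(ac50 = NA_real_, hill = NA_real_, top = NA_real_,
        bottom = NA_real_, r2 = NA_real_, converged = FALSE,
        direction = "none", curve_class = "4", efficacy = 0,
        max_resp = mx, n_masked = 0L)
    } else {
      f <- fit_hill(conc, resp)
      .(ac50 = f$ac50, hill = f$hill, top = f$top, bottom = f$bottom,
        r2 = f$r2, converged = f$converged, direction = f$direction,
        curve_class = classify_curve(f, conc, resp, ns),
        efficacy = efficacy(f), max_resp = mx,
        n_masked = length(f$masked_points))
    }
  }, by = .(assay_id, run, sample_id, compound_id)]
  data.table::setattr(fits, "noise_sd", noise_sd)
  data.table::setattr(fits, "class", c("screen_fits", class(fits)))
  fits[]
}

#' Autofluorescence profile of each sample
#'
#' Median-across-runs normalized fluorescence of every sample in the three
#' autofluorescence counter-screen channels, per concentration. Used to
#' demote reporter-assay activation calls caused by compound fluorescence in
#' the assay's detection channels.
#'
#' @param normalized a [normalize_screen()] result.
#' @return `data.table`: `sample_id`, `channel`, `concentration_M`,
#'   `activity` (median over runs).
#' @export
autofluor_profile <- function(normalized) {
  norm <- normalized$normalized
  af <- norm[role == "compound" &
               assay_id %in% c("autofluor_blue", "autofluor_green",
                               "autofluor_red")]
  af[, channel := sub("autofluor_", "", assay_id)]
  af[, .(activity = stats::median(activity)),
     by = .(sample_id, channel, concentration_M)]
}
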