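#' Screen configuration
#'
#' Builds the single configuration object consumed by every stage of the
#' pipeline: library size and truth-class mixture, the concentration grid,
#' the noise model, plate geometry and the random seed.
#'
#' Defaults describe a desk-scale stand-in for a ~10K environmental-chemical
#' qHTS campaign: 1,000 compounds tested as 15-point titrations from 1.1 nM
#' to 92 uM in 1536-well plates, three independent runs with permuted well
#' positions, and 88 compounds duplicated on every plate as internal
#' reproducibility controls.
#'
#' @param n_compounds number of library compounds.
#' @param mixture named numeric vector of truth-class proportions; must sum
#'   to 1. Classes: `full_agonist`, `partial_agonist`, `antagonist`,
#'   `cytotoxic_only`, `autofluorescent`, `selective_modulator`, `inactive`.
#' @param n_conc,c_min,c_max concentration grid: number of points and molar
#'   endpoints (geometric spacing).
#' @param noise_cv multiplicative log-normal noise, percent CV of raw signal.
#' @param noise_add additive noise, as a fraction of the plate baseline.
#' @param plate_effect_cv per-plate random multiplier, percent CV.
#' @param n_duplicates number of compounds plated twice per run as internal
#'   duplicate controls.
#' @param n_runs number of independent screen runs.
#' @param plate_rows,plate_cols plate geometry (default 1536-well).
#' @param fingerprint_bits length of the binary structural fingerprint.
#' @param family_size mean structural-family size used to seed fingerprints.
#' @param bit_flip_prob per-bit flip probability applied to a family
#'   prototype when drawing a member fingerprint.
#' @param planted_agonist_family,planted_confound_family sizes of the two
#'   deterministic planted families (a full-agonist family and a mixed
#'   antagonist/cytotoxic family) used to validate enrichment recovery;
#'   set to 0 to disable.
#' @param stim_frac fractional receptor stimulation (of the positive
#'   control's maximum) applied to antagonist-mode wells.
#' @param cytotox_window AC50 ratio within which an antagonist call is
#'   demoted to cytotoxicity-confounded when the viability curve declines.
#' @param seed integer seed; together with the config it fully determines
#'   every downstream artifact.
#' @return object of class `screen_config` (a validated list).
#' @export
screen_config <- function(n_compounds = 1000,
                          mixture = c(full_agonist = 0.08,
                                      partial_agonist = 0.05,
                                      antagonist = 0.05,
                                      cytotoxic_only = 0.05,
                                      autofluorescent = 0.02,
                                      selective_modulator = 0.02,
                                      inactive = 0.73),
                          n_conc = 15,
                          c_min = 1.1e-9,
                          c_max = 9.2e-5,
                          noise_cv = 7,
                          noise_add = 0.01,
                          plate_effect_cv = 3,
                          n_duplicates = 88,
                          n_runs = 3,
                          plate_rows = 32,
                          plate_cols = 48,
                          fingerprint_bits = 512,
                          family_size = 12,
                          bit_flip_prob = 0.05,
                          planted_agonist_family = 30,
                          planted_confound_family = 30,
                          stim_frac = 0.8,
                          cytotox_window = 3,
                          seed = 1L) {
  classes <- c("full_agonist", "partial_agonist", "antagonist",
               "cytotoxic_only", "autofluorescent", "selective_modulator",
               "inactive")
  if (is.null(names(mixture)) || !all(names(mixture) %in% classes))
    stop("mixture must be named with valid truth classes", call. = FALSE)
  full <- stats::setNames(numeric(length(classes)), classes)
  full[names(mixture)] <- mixture
  if (any(full < 0) || abs(sum(full) - 1) > 1e-8)
    stop("mixture proportions must be non-negative and sum to 1",
         call. = FALSE)
  if (n_conc < 4) stop("n_conc must be >= 4", call. = FALSE)
  if (!(c_min < c_max)) stop("c_min must be < c_max", call. = FALSE)
  if (n_duplicates > n_compounds)
    stop("n_duplicates cannot exceed n_compounds", call. = FALSE)
  cfg <- list(n_compounds = as.integer(n_compounds),
              mixture = full,
              n_conc = as.integer(n_conc), c_min = c_min, c_max = c_max,
              noise_cv = noise_cv, noise_add = noise_add,
              plate_effect_cv = plate_effect_cv,
              n_duplicates = as.integer(n_duplicates),
              n_runs = as.integer(n_runs),
              plate_rows = as.integer(plate_rows),
              plate_cols = as.integer(plate_cols),
              fingerprint_bits = as.integer(fingerprint_bits),
              family_size = family_size,
              bit_flip_prob = bit_flip_prob,
              planted_agonist_family = as.integer(planted_agonist_family),
              planted_confound_family = as.integer(planted_confound_family),
              stim_frac = stim_frac,
              cytotox_window = cytotox_window,
              seed = as.integer(seed))
  class(cfg) <- "screen_config"
  cfg
}

#' @export
print.screen_config <- function(x, ...) {
  cat("qHTS screen configuration\n")
  cat(sprintf("  compounds: %d (+%d duplicates), runs: %d, seed: %d\n",
              x$n_compounds, x$n_duplicates, x$n_runs, x$seed))
  cat(sprintf("  titration: %d points, %.3g to %.3g M\n",
              x$n_conc, x$c_min, x$c_max))
  cat(sprintf("  noise: CV %.1f%%, plate effect %.1f%%\n",
              x$noise_cv, x$plate_effect_cv))
  invisible(x)
}

#' Geometric concentration grid
#'
#' Ordered molar test concentrations: a geometric series between the two
#' endpoints (for the default grid, 15 points from 1.1 nM to 92 uM, adjacent
#' step ratio about 2.25).
#'
#' @param config a [screen_config()], or `NULL` to use `n`, `c_min`, `c_max`.
#' @param n,c_min,c_max overrides when no config is given.
#' @return numeric vector of strictly increasing molar concentrations.
#' @export
concentration_grid <- function(config = NULL, n = 15, c_min = 1.1e-9,
                               c_max = 9.2e-5) {
  if (!is.null(config)) {
    n <- config$n_conc; c_min <- config$c_min; c_max <- config$c_max
  }
  if (n < 2) stop("need at least 2 concentrations", call. = FALSE)
  if (!(c_min < c_max)) stop("c_min must be < c_max", call. = FALSE)
  exp(seq(log(c_min), log(c_max), length.out = n))
}

#' Assay panel metadata
#'
#' One row per assay readout in the screen: the two reporter platforms
#' (`bla`, a FRET beta-lactamase reporter read in blue/green fluorescence
#' channels; `luc`, a luciferase reporter) each in agonist and antagonist
#' mode, their multiplexed viability readouts, and the three
#' autofluorescence channels. Raw-signal levels and embedded
#' positive-control parameters echo typical reporter-assay windows
#' (agonist control: a reference full agonist such as 17beta-estradiol;
#' antagonist control: a reference antagonist such as 4-hydroxytamoxifen;
#' viability control: a cytotoxic quaternary ammonium salt).
#'
#' @return data.frame with columns `assay_id`, `platform`, `mode`,
#'   `direction` (expected sign of true effects), `base` and `top` raw
#'   signal levels, control Hill parameters and detection channel.
#' @export
assay_table <- function() {
  data.frame(
    assay_id = c("bla_agonist", "bla_antagonist", "bla_viability",
                 "luc_agonist", "luc_antagonist", "luc_viability",
                 "autofluor_blue", "autofluor_green", "autofluor_red"),
    platform = c("bla", "bla", "bla", "luc", "luc", "luc",
                 "auto", "auto", "auto"),
    mode = c("agonist", "antagonist", "viability",
             "agonist", "antagonist", "viability",
             "autofluor", "autofluor", "autofluor"),
    direction = c(1, -1, -1, 1, -1, -1, 1, 1, 1),
    base = c(100, 120, 1000, 200, 100, 600, 50, 50, 50),
    top = c(460, 465, 7.5, 500, 975, 100, 550, 550, 550),
    control_ac50 = c(3.14e-10, 5.01e-9, 1e-5,
                     2.74e-11, 7.3e-8, 1e-5,
                     1e-6, 1e-6, 1e-6),
    control_hill = c(1.2, 1.2, 2, 1.2, 1.2, 2, 1, 1, 1),
    channel = c("blue_green", "blue_green", "none",
                "lum", "lum", "green",
                "blue", "green", "red"),
    stringsAsFactors = FALSE
  )
}

# deterministic 32-bit sub-seed for stage k of a run
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k) %% 2147483647)
}
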