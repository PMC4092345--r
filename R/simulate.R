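#' @keywords internal
hill_theta <- function(conc, ac50, hill = 1.2) {
  n <- max(length(conc), length(ac50), length(hill))
  conc <- rep_len(conc, n); ac50 <- rep_len(ac50, n)
  hill <- rep_len(hill, n)
  out <- numeric(n)
  ok <- !is.na(ac50)
  out[ok] <- 1 / (1 + (ac50[ok] / conc[ok])^hill[ok])
  out
}

# Noise-free expected raw signal for compound wells; all arguments vectors of
# equal length except `assay_id` (scalar) and `config`.
expected_signal <- function(lib, assay_id, conc, config) {
  at <- assay_table()
  a <- at[at$assay_id == assay_id, ]
  if (nrow(a) != 1) stop("unknown assay_id: ", assay_id, call. = FALSE)
  base <- a$base; top <- a$top
  theta_cyto <- hill_theta(conc, lib$cytotox_ac50, hill = 3)
  viab <- 1 - theta_cyto

  if (a$mode == "agonist") {
    dir <- if (a$platform == "bla") lib$er_dir_bla else lib$er_dir_luc
    ac50 <- if (a$platform == "bla") lib$er_ac50_bla else lib$er_ac50_luc
    frac <- ifelse(dir == "agonist",
                   (lib$er_eff / 100) * hill_theta(conc, ac50), 0)
    sig <- base + (top - base) * frac
  } else if (a$mode == "antagonist") {
    dir <- if (a$platform == "bla") lib$er_dir_bla else lib$er_dir_luc
    ac50 <- if (a$platform == "bla") lib$er_ac50_bla else lib$er_ac50_luc
    theta <- ifelse(dir == "none", 0, hill_theta(conc, ac50))
    f <- config$stim_frac * (1 - theta) + (lib$er_eff / 100) * theta
    sig <- base + (top - base) * f * viab
  } else if (a$mode == "viability") {
    sig <- base * viab + top * theta_cyto
  } else { # autofluor channel
    sig <- rep(base, length(conc))
  }

  # autofluorescence: concentration-proportional offset in matching channels
  ch <- switch(a$channel, blue_green = c("blue", "green"),
               blue = "blue", green = "green", red = "red", character(0))
  if (length(ch) > 0 && any(nzchar(lib$autofluor_channels))) {
    has <- vapply(strsplit(lib$autofluor_channels, ";"),
                  function(x) any(x %in% ch), logical(1))
    sig <- sig + ifelse(has, lib$autofluor_amp * conc / config$c_max, 0)
  }
  sig
}

#' Simulate one concentration-response titration
#'
#' Noise-free or noisy raw readout for a single compound in a single assay,
#' using the same response model as the full screen assembly: Hill-shaped
#' activation toward the compound's true efficacy in agonist mode,
#' competitive displacement of the stimulated signal in antagonist mode,
#' shared-AC50 signal and viability loss for cytotoxic compounds, and
#' channel-matched concentration-proportional autofluorescence offsets.
#'
#' @param compound one row of the `compounds` table from
#'   [generate_library()] (a 1-row data.frame).
#' @param assay_id one of the ids in [assay_table()].
#' @param concentrations molar concentrations (default: the config grid).
#' @param config a [screen_config()].
#' @param noise logical; apply the config noise model.
#' @param seed seed used when `noise = TRUE`.
#' @return data.frame with `concentration_M` and raw `signal`.
#' @export
simulate_response <- function(compound, assay_id, concentrations = NULL,
                              config = screen_config(), noise = TRUE,
                              seed = config$seed) {
  if (is.null(concentrations)) concentrations <- concentration_grid(config)
  lib <- compound[rep(1L, length(concentrations)), , drop = FALSE]
  sig <- expected_signal(lib, assay_id, concentrations, config)
  if (noise) {
    at <- assay_table()
    base <- at$base[at$assay_id == assay_id]
    sig <- withr::with_seed(seed, add_noise(sig, base, config))
  }
  data.frame(concentration_M = concentrations, signal = sig)
}

add_noise <- function(sig, base, config, plate_mult = 1) {
  n <- length(sig)
  out <- sig * plate_mult * exp(stats::rnorm(n, 0, config$noise_cv / 100)) +
    stats::rnorm(n, 0, config$noise_add * base)
  pmax(out, 1e-9)
}

# 16-point control titration grid centred on the control AC50
control_grid <- function(ac50, span = 300, n = 16) {
  exp(seq(log(ac50 / span), log(ac50 * span), length.out = n))
}

#' Assemble the raw plate readouts for a full screen
#'
#' Lays the library out on plates and simulates every readout of every run.
#' The layout is an inter-plate titration: within one run each sample owns a
#' fixed well slot, and the stack of `n_conc` plates per assay carries the
#' titration (plate \emph{k} holds test concentration \emph{k} for every
#' sample). Well slots are permuted independently per run. Every plate
#' carries 16 negative-control wells and the positive-control titration
#' (16 concentrations in duplicate); duplicate-control compounds appear
#' twice per run.
#'
#' @param library a [generate_library()] result.
#' @param config the matching [screen_config()].
#' @param noise logical; apply the noise model (multiplicative well noise,
#'   additive noise, per-plate random effect).
#' @return `data.table` of class `screen_raw` with one row per well:
#'   `plate_id`, `assay_id`, `run`, `conc_index`, `well`, `row`, `col`,
#'   `role` (`compound`/`neg`/`pos`), `sample_id`, `compound_id`,
#'   `concentration_M`, `signal`.
#' @export
assemble_runs <- function(library, config, noise = TRUE) {
  stopifnot(inherits(library, "screen_library"))
  comp <- library$compounds
  at <- assay_table()
  n_ctrl_wells <- 48L
  capacity <- config$plate_rows * config$plate_cols - n_ctrl_wells
  if (capacity < 1) stop("plate geometry leaves no compound wells",
                         call. = FALSE)

  dup_ids <- comp$compound_id[comp$is_duplicate_control]
  samples <- data.table::data.table(
    sample_id = c(comp$compound_id, paste0(dup_ids, ".b")),
    compound_id = c(comp$compound_id, dup_ids))
  n_samp <- nrow(samples)
  n_stacks <- ceiling(n_samp / capacity)
  grid <- concentration_grid(config)

  runs <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    perm <- withr::with_seed(derive_seed(config$seed, 100L + r),
                             sample.int(n_samp))
    smp <- data.table::copy(samples)
    smp[, gslot := perm]
    smp[, stack := (gslot - 1L) %/% capacity + 1L]
    smp[, well := (gslot - 1L) %% capacity + n_ctrl_wells + 1L]

    per_assay <- lapply(at$assay_id, function(aid) {
      dt <- smp[rep(seq_len(n_samp), each = config$n_conc)]
      dt[, conc_index := rep(seq_len(config$n_conc), times = n_samp)]
      dt[, concentration_M := grid[conc_index]]
      dt[, assay_id := aid]
      dt[, role := "compound"]
      lib_rows <- comp[match(dt$compound_id, comp$compound_id), ]
      dt[, expected := expected_signal(lib_rows, aid, concentration_M,
                                       config)]
      a <- at[at$assay_id == aid, ]
      # per-plate controls
      stim <- a$base + (a$top - a$base) * config$stim_frac
      from <- if (a$mode == "antagonist") stim else a$base
      to <- if (a$mode == "antagonist") a$base else a$top
      cg <- control_grid(a$control_ac50)
      theta <- hill_theta(cg, a$control_ac50, a$control_hill)
      plates <- data.table::CJ(stack = seq_len(n_stacks),
                               conc_index = seq_len(config$n_conc))
      ctrl <- plates[rep(seq_len(nrow(plates)), each = n_ctrl_wells)]
      ctrl[, well := rep(seq_len(n_ctrl_wells), times = nrow(plates))]
      ctrl[, role := data.table::fifelse(well <= 16L, "neg", "pos")]
      ctrl[, sample_id := NA_character_]
      ctrl[, compound_id := NA_character_]
      ctrl_ci <- rep(c(rep(NA_integer_, 16L), rep(1:16, 2L)),
                     times = nrow(plates))
      ctrl[, concentration_M := data.table::fifelse(role == "pos",
                                                    cg[ctrl_ci], NA_real_)]
      ctrl[, expected := data.table::fifelse(
        role == "neg", from, from + (to - from) * theta[ctrl_ci])]
      ctrl[, assay_id := aid]
      out <- rbind(dt[, .(stack, conc_index, well, role, sample_id,
                          compound_id, concentration_M, expected, assay_id)],
                   ctrl[, .(stack, conc_index, well, role, sample_id,
                            compound_id, concentration_M, expected,
                            assay_id)])
      out
    })
    dt <- data.table::rbindlist(per_assay)
    dt[, run := r]
    runs[[r]] <- dt
  }
  raw <- data.table::rbindlist(runs)
  raw[, plate_id := sprintf("%s_r%d_s%d_p%02d", assay_id, run, stack,
                            conc_index)]
  raw[, row := (well - 1L) %% config$plate_rows + 1L]
  raw[, col := (well - 1L) %/% config$plate_rows + 1L]

  if (noise) {
    data.table::setorder(raw, plate_id, well)
    base_map <- stats::setNames(at$base, at$assay_id)
    withr::with_seed(derive_seed(config$seed, 200L), {
      plate_ids <- unique(raw$plate_id)
      pm <- stats::setNames(
        exp(stats::rnorm(length(plate_ids), 0,
                         config$plate_effect_cv / 100)), plate_ids)
      raw[, signal := add_noise(expected, base_map[assay_id], config,
                                pm[plate_id])]
    })
  } else {
    raw[, signal := pmax(expected, 1e-9)]
  }
  raw[, expected := NULL]
  raw[, stack := NULL]
  data.table::setcolorder(raw, c("plate_id", "assay_id", "run", "conc_index",
                                 "well", "row", "col", "role", "sample_id",
                                 "compound_id", "concentration_M", "signal"))
  data.table::setattr(raw, "class", c("screen_raw", class(raw)))
  raw[]
}
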