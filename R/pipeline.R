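#' Run the full screening pipeline
#'
#' Simulate -> normalize -> fit -> call -> reconcile -> evaluate -> enrich,
#' end to end from one configuration and one seed, optionally persisting
#' every stage as plain CSV/JSON files plus a run manifest with file
#' digests and stage timings. Identical config and seed reproduce identical
#' outputs.
#'
#' @param config a [screen_config()].
#' @param out_dir directory for stage outputs, or `NULL` to keep results in
#'   memory only.
#' @param noise logical; apply the noise model.
#' @param enrich logical; run SOM clustering and enrichment (the slowest
#'   optional stage).
#' @return list of class `screen_run` with elements `library`, `raw`,
#'   `normalized`, `plate_stats`, `control_ac50`, `fits`, `calls`,
#'   `reconciled`, `reproducibility`, `duplicates`, `distribution`,
#'   `reference`, `binding`, `som`, `enrichment`, `manifest`.
#' @export
run_screen <- function(config, out_dir = NULL, noise = TRUE,
                       enrich = TRUE) {
  stopifnot(inherits(config, "screen_config"))
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  lib <- generate_library(config)
  raw <- assemble_runs(lib, config, noise = noise)
  timings["simulate"] <- tic() - t0

  t0 <- tic()
  norm <- normalize_screen(raw)
  ctrl <- control_titration_ac50(norm)
  timings["normalize"] <- tic() - t0

  t0 <- tic()
  fits <- fit_screen(norm, config)
  timings["fit"] <- tic() - t0

  t0 <- tic()
  calls <- call_screen(fits, norm, config)
  reconciled <- reconcile_screen(fits)
  timings["call"] <- tic() - t0

  t0 <- tic()
  repro <- reproducibility_summary(reconciled)
  dups <- duplicate_concordance(calls, lib)
  distribution <- outcome_distribution(calls)
  er_assays <- c("bla_agonist", "bla_antagonist", "luc_agonist",
                 "luc_antagonist")
  reference <- lapply(stats::setNames(er_assays, er_assays), function(a)
    reference_performance(calls, lib, a))
  binding <- lapply(stats::setNames(c("bla", "luc"), c("bla", "luc")),
                    function(p) binding_concordance(calls, lib, p))
  timings["evaluate"] <- tic() - t0

  som <- NULL; enr <- NULL
  if (enrich) {
    t0 <- tic()
    som <- train_som(lib$fingerprints, seed = derive_seed(config$seed, 5L))
    enr <- enrichment_matrix(som$assignments, calls, lib)
    timings["enrich"] <- tic() - t0
  }

  run <- list(library = lib, raw = raw, normalized = norm$normalized,
              plate_stats = norm$plate_stats, control_ac50 = ctrl,
              fits = fits, calls = calls, reconciled = reconciled,
              reproducibility = repro, duplicates = dups,
              distribution = distribution, reference = reference,
              binding = binding, som = som, enrichment = enr)
  run$manifest <- build_manifest(config, timings)
  class(run) <- "screen_run"
  if (!is.null(out_dir)) write_screen(run, out_dir)
  run
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

build_manifest <- function(config, timings) {
  list(config = unclass(config),
       config_hash = config_hash(config),
       seed = config$seed,
       timings_s = as.list(round(timings, 3)),
       version = as.character(utils::packageVersion("qhtsER")),
       files = list())
}

#' Persist a screen run as plain files
#'
#' Writes the library, fingerprints, raw readouts, normalized activities,
#' plate statistics, fits, calls, reconciliation, outcome distribution,
#' enrichment matrix and metrics to CSV/JSON under `out_dir`, and a
#' `manifest.json` with an md5 digest of every file.
#'
#' @param run a [run_screen()] result.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the manifest.
#' @export
write_screen <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) {
    path <- file.path(out_dir, f)
    data.table::fwrite(x, path)
    path
  }
  files <- c(
    w(run$library$compounds, "library.csv"),
    w(data.table::as.data.table(run$library$fingerprints),
      "fingerprints.csv"),
    w(run$raw, "raw.csv"),
    w(run$normalized, "normalized.csv"),
    w(run$plate_stats, "plate_stats.csv"),
    w(run$fits, "fits.csv"),
    w(run$calls, "calls.csv"),
    w(run$reconciled, "reconciliation.csv"),
    w(run$distribution, "outcome_distribution.csv"))
  if (!is.null(run$enrichment)) {
    files <- c(files, w(data.table::as.data.table(run$enrichment,
                                                  keep.rownames = "node"),
                        "enrichment_matrix.csv"))
  }
  metrics <- list(
    plate_stats_mean = as.list(colMeans(
      run$plate_stats[, .(s_b, cv, z_prime)], na.rm = TRUE)),
    control_ac50 = run$control_ac50$summary,
    reproducibility = run$reproducibility,
    duplicates = run$duplicates$summary,
    reference = lapply(run$reference, function(r)
      r[c("tp", "fp", "tn", "fn", "sensitivity", "specificity",
          "accuracy", "fisher_p", "n_inconclusive")]),
    binding = lapply(run$binding, function(b)
      b[c("cp", "dp", "cn", "dn", "n_inconclusive", "concordance",
          "fisher_p")]))
  mpath <- file.path(out_dir, "metrics.json")
  jsonlite::write_json(metrics, mpath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  files <- c(files, mpath)
  run$manifest$files <- as.list(tools::md5sum(files))
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(run$manifest)
}

#' @export
print.screen_run <- function(x, ...) {
  cat(sprintf("screen_run: %d compounds, %d runs (seed %d)\n",
              nrow(x$library$compounds), x$manifest$config$n_runs,
              x$manifest$seed))
  cat(sprintf("  mean plate Z': %.2f\n",
              mean(x$plate_stats$z_prime, na.rm = TRUE)))
  cat("  activity outcomes (% per endpoint):\n")
  print(data.table::dcast(x$distribution, outcome ~ assay_id,
                          value.var = "percent", fill = 0))
  invisible(x)
}
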