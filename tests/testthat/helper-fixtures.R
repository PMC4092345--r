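library(data.table)

# small plate geometry keeps test screens fast (384-well: 336 compound wells)
small_config <- function(n = 60, seed = 42, ...) {
  screen_config(n_compounds = n, n_duplicates = max(4L, n %/% 10),
                plate_rows = 16, plate_cols = 24, seed = seed, ...)
}

# independent two-sided Fisher oracle: enumerate all tables with the observed
# margins and sum hypergeometric probabilities not exceeding the observed one
brute_fisher <- function(a, b, c, d) {
  m <- a + c; nn <- b + d; k <- a + b
  lo <- max(0, k - nn); hi <- min(k, m)
  x <- lo:hi
  pr <- stats::dhyper(x, m, nn, k)
  p_obs <- stats::dhyper(a, m, nn, k)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# noiseless normalized activity for a compound titration, computed from the
# assay's known control levels (the generating model, not normalize_screen)
truth_activity <- function(sig, assay_id, stim_frac = 0.8) {
  at <- assay_table()
  a <- at[at$assay_id == assay_id, ]
  if (a$mode == "antagonist") {
    stim <- a$base + (a$top - a$base) * stim_frac
    100 * (sig - stim) / (stim - a$base)
  } else if (a$mode == "viability") {
    100 * (sig - a$base) / abs(a$top - a$base)
  } else {
    100 * (sig - a$base) / (a$top - a$base)
  }
}

# hill_fit constructor for accessor tests
make_fit <- function(ac50 = 1e-7, hill = 1, top = 100, bottom = 0,
                     r2 = 0.99, converged = TRUE,
                     direction = if (top >= bottom) "activation" else
                       "inhibition") {
  structure(list(ac50 = ac50, hill = hill, top = top, bottom = bottom,
                 r2 = r2, converged = converged, direction = direction,
                 masked_points = integer(0), rss = 0),
            class = "hill_fit")
}
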