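#' Four-parameter Hill response
#'
#' `y = bottom + (top - bottom) / (1 + (ac50/c)^hill)`; the standard
#' concentration-response model on the percent-activity scale.
#'
#' @param conc molar concentrations.
#' @param ac50 molar concentration at half-maximal response.
#' @param hill Hill slope.
#' @param top,bottom asymptotes (percent activity).
#' @return numeric responses.
#' @export
hill_response <- function(conc, ac50, hill = 1, top = 100, bottom = 0) {
  bottom + (top - bottom) / (1 + (ac50 / conc)^hill)
}

hill_sse <- function(par, lc, y) {
  pred <- par[4] + (par[3] - par[4]) / (1 + 10^(par[2] * (par[1] - lc)))
  sum((y - pred)^2)
}

#' Fit the Hill model to a titration
#'
#' Bounded nonlinear least squares (L-BFGS-B) on percent activity with three
#' multi-start initialisations (AC50 started at the grid quartiles). Bounds:
#' AC50 within `[min(conc)/100, max(conc)*100]`, Hill slope in `[0.3, 8]`,
#' asymptotes in `[-150, 150]`. The fit is reported unconverged when it does
#' not improve on the flat (constant) model by at least 5\% of the total sum
#' of squares. One-point outlier masking is attempted when the initial fit is
#' poor and is kept only if it improves R-squared by at least 0.2.
#'
#' @param concentration molar concentrations (>= 4 points).
#' @param response percent activity, same length.
#' @param allow_mask logical; permit masking a single outlying point.
#' @return object of class `hill_fit`: list with `ac50`, `hill`, `top`,
#'   `bottom`, `r2`, `converged`, `direction` (`"activation"`,
#'   `"inhibition"` or `"none"`), `masked_points` (integer indices) and
#'   `rss`.
#' @export
fit_hill <- function(concentration, response, allow_mask = TRUE) {
  if (length(concentration) < 4)
    stop("need at least 4 concentration points", call. = FALSE)
  if (length(concentration) != length(response))
    stop("concentration and response lengths differ", call. = FALSE)
  o <- order(concentration)
  concentration <- concentration[o]; response <- response[o]
  fit <- .fit_hill_core(concentration, response)
  fit$masked_points <- integer(0)
  if (allow_mask && fit$converged && fit$r2 < 0.9 &&
      length(response) >= 5) {
    pred <- hill_response(concentration, fit$ac50, fit$hill, fit$top,
                          fit$bottom)
    drop <- which.max(abs(response - pred))
    refit <- .fit_hill_core(concentration[-drop], response[-drop])
    if (refit$converged && refit$r2 - fit$r2 >= 0.2) {
      refit$masked_points <- o[drop]
      fit <- refit
    }
  }
  fit
}

.fit_hill_core <- function(concentration, response) {
  lc <- log10(concentration)
  n <- length(response)
  sst <- sum((response - mean(response))^2)
  lo <- c(min(lc) - 2, 0.3, -150, -150)
  hi <- c(max(lc) + 2, 8, 150, 150)
  top0 <- mean(response[(n - 2):n])
  bot0 <- mean(response[1:3])
  qs <- stats::quantile(lc, c(0.25, 0.5, 0.75), names = FALSE)
  best <- NULL
  for (la0 in qs) {
    par0 <- pmin(pmax(c(la0, 1.3, top0, bot0), lo), hi)
    res <- tryCatch(
      stats::optim(par0, hill_sse, lc = lc, y = response,
                   method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value))
      best <- res
  }
  if (is.null(best)) {
    return(structure(list(ac50 = NA_real_, hill = NA_real_, top = NA_real_,
                          bottom = NA_real_, r2 = NA_real_,
                          converged = FALSE, direction = "none",
                          masked_points = integer(0), rss = NA_real_),
                     class = "hill_fit"))
  }
  p <- best$par
  rss <- best$value
  r2 <- if (sst > 0) 1 - rss / sst else NA_real_
  converged <- sst > 1e-8 && (sst - rss) / sst >= 0.05 &&
    abs(p[3] - p[4]) > 1e-6
  direction <- if (!converged) "none" else
    if (p[3] > p[4]) "activation" else "inhibition"
  structure(list(ac50 = 10^p[1], hill = p[2], top = p[3], bottom = p[4],
                 r2 = r2, converged = converged, direction = direction,
                 masked_points = integer(0), rss = rss),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$converged) {
    cat("hill_fit: not converged (no concentration response)\n")
  } else {
    cat(sprintf(
      "hill_fit: AC50 %.3g M, hill %.2f, top %.1f, bottom %.1f, R2 %.3f (%s)\n",
      x$ac50, x$hill, x$top, x$bottom, x$r2, x$direction))
  }
  invisible(x)
}

#' Efficacy and potency accessors
#'
#' Efficacy is the magnitude of the fitted response span `|top - bottom|` on
#' the control-normalized percent scale (so a partial agonist plateauing at
#' 22\% of the positive-control maximum has efficacy 22, and full inhibition
#' to -100 has efficacy 100). Potency is the fitted AC50 in molar; `NA` for
#' unconverged fits.
#'
#' @param fit a [fit_hill()] result.
#' @return numeric scalar.
#' @export
efficacy <- function(fit) {
  if (!fit$converged) return(0)
  abs(fit$top - fit$bottom)
}

#' @rdname efficacy
#' @export
potency <- function(fit) {
  if (!fit$converged) return(NA_real_)
  fit$ac50
}

#' Grade a concentration-response curve
#'
#' Assigns the categorical curve class used to weight confidence in
#' downstream activity calls:
#' \describe{
#'   \item{4}{inactive: no response exceeding `max(3 * noise_sd, 20)`.}
#'   \item{1.1 / 1.2}{complete curve (both asymptotes within the tested
#'     range, fitted plateau reached, R2 >= 0.9); `.1` at efficacy >= 80,
#'     `.2` below.}
#'   \item{2.1 / 2.2}{incomplete curve (only the lower asymptote supported,
#'     or R2 in `[0.6, 0.9)`); split at 80 on the maximal observed
#'     response.}
#'   \item{3}{significant response but unfittable: R2 < 0.6, unconverged
#'     fit, or only the single highest concentration responds.}
#' }
#'
#' @param fit a [fit_hill()] result.
#' @param concentration,response the fitted titration.
#' @param noise_sd assay noise level on the percent-activity scale.
#' @return character scalar: `"1.1"`, `"1.2"`, `"2.1"`, `"2.2"`, `"3"` or
#'   `"4"`.
#' @export
classify_curve <- function(fit, concentration, response, noise_sd = 5) {
  thr <- max(3 * noise_sd, 20)
  if (length(fit$masked_points) > 0) {
    keep <- setdiff(seq_along(response), fit$masked_points)
    response_eff <- response[keep]
  } else response_eff <- response
  max_resp <- max(abs(response_eff))
  if (max_resp < thr) return("4")
  if (!fit$converged) return("3")
  sig <- which(abs(response_eff) >= thr)
  if (length(sig) == 1 && sig == length(response_eff)) return("3")
  if (fit$r2 < 0.6) return("3")
  cmin <- min(concentration); cmax <- max(concentration)
  plateau <- 1 / (1 + (fit$ac50 / cmax)^fit$hill)
  complete <- fit$r2 >= 0.9 && fit$ac50 >= cmin && fit$ac50 <= cmax &&
    plateau >= 0.9
  if (complete) {
    if (efficacy(fit) >= 80) "1.1" else "1.2"
  } else {
    if (max_resp >= 80) "2.1" else "2.2"
  }
}
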