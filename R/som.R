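#' Train a self-organizing map on binary fingerprints
#'
#' Compact batch SOM: the codebook is initialised from randomly sampled
#' fingerprint rows (plus a small deterministic jitter), then updated for
#' `epochs` batch rounds with a Gaussian grid neighbourhood whose radius
#' decays linearly to 0.5. Final cluster assignment uses Hamming distance
#' to the codebook thresholded at 0.5 (binary-fingerprint semantics), ties
#' broken by the lowest node index. Deterministic given `seed`.
#'
#' @param fingerprints 0/1 matrix, one compound per row.
#' @param grid_dim `c(rows, cols)` of the map; default sizes the map to
#'   roughly one node per 13 compounds (the granularity at which a ~8K
#'   library yields several hundred structure clusters).
#' @param epochs number of batch training rounds.
#' @param seed integer seed.
#' @return object of class `som_model`: `codebook` (continuous),
#'   `codebook_bin`, `grid_dim`, `assignments` (node index per row),
#'   `seed`.
#' @export
train_som <- function(fingerprints, grid_dim = NULL, epochs = 20,
                      seed = 1L) {
  fp <- as.matrix(fingerprints)
  n <- nrow(fp)
  if (n == 0) stop("empty fingerprint matrix", call. = FALSE)
  if (is.null(grid_dim)) {
    side <- max(2L, as.integer(round(sqrt(n / 13))))
    grid_dim <- c(side, side)
  }
  m <- prod(grid_dim)
  coords <- cbind(rep(seq_len(grid_dim[1]), times = grid_dim[2]),
                  rep(seq_len(grid_dim[2]), each = grid_dim[1]))
  gd2 <- as.matrix(stats::dist(coords))^2

  withr::with_seed(seed, {
    init_rows <- sample.int(n, m, replace = m > n)
    W <- fp[init_rows, , drop = FALSE] +
      matrix(stats::runif(m * ncol(fp), 0, 0.01), nrow = m)
    r0 <- max(grid_dim) / 2
    x2 <- rowSums(fp^2)
    for (e in seq_len(epochs)) {
      d2 <- outer(x2, rowSums(W^2), "+") - 2 * tcrossprod(fp, W)
      bmu <- max.col(-d2, ties.method = "first")
      sigma <- max(0.5, r0 + (0.5 - r0) * (e - 1) / max(1, epochs - 1))
      H <- exp(-gd2 / (2 * sigma^2))
      B <- matrix(0, n, m); B[cbind(seq_len(n), bmu)] <- 1
      S <- crossprod(B, fp)            # per-node sums
      cnt <- colSums(B)
      numer <- H %*% S
      denom <- as.numeric(H %*% cnt)
      upd <- denom > 1e-12
      W[upd, ] <- numer[upd, , drop = FALSE] / denom[upd]
    }
  })
  Wb <- (W >= 0.5) * 1L
  model <- structure(list(codebook = W, codebook_bin = Wb,
                          grid_dim = grid_dim, seed = seed),
                     class = "som_model")
  model$assignments <- som_assign(model, fp)
  model
}

#' Assign fingerprints to SOM nodes
#'
#' Nearest node by Hamming distance to the binarised codebook; ties go to
#' the lowest node index.
#'
#' @param model a [train_som()] result.
#' @param fingerprints 0/1 matrix.
#' @return integer node index per row.
#' @export
som_assign <- function(model, fingerprints) {
  fp <- as.matrix(fingerprints)
  Wb <- model$codebook_bin
  # Hamming = |x| + |w| - 2 x.w for binary vectors
  d <- outer(rowSums(fp), rowSums(Wb), "+") - 2 * tcrossprod(fp, Wb)
  max.col(-d, ties.method = "first")
}

#' Per-node enrichment of an activity category
#'
#' For every node, tests the 2x2 table (in node vs out of node) x (in
#' category vs not) with the two-sided Fisher exact test. A node is
#' enriched when p is below `p_threshold` and the in-node category rate
#' exceeds the background rate. The signed log10 p (positive for
#' over-representation, negative for depletion) feeds the heatmap-ready
#' enrichment matrix.
#'
#' @param assignments integer node per compound.
#' @param in_category logical per compound.
#' @param n_nodes number of nodes (defaults to `max(assignments)`).
#' @param p_threshold enrichment significance threshold.
#' @return `data.table`: `node`, `n_node`, `n_hit` (in-node category
#'   count), `n_hit_bg`, `p`, `enriched`, `log10_p_signed`.
#' @export
cluster_enrichment <- function(assignments, in_category,
                               n_nodes = max(assignments),
                               p_threshold = 0.01) {
  stopifnot(length(assignments) == length(in_category))
  res <- lapply(seq_len(n_nodes), function(j) {
    inn <- assignments == j
    a <- sum(inn & in_category); b <- sum(inn & !in_category)
    cc <- sum(!inn & in_category); d <- sum(!inn & !in_category)
    p <- as.numeric(fisher_exact_2x2(a, b, cc, d))
    over <- (a + b) > 0 && (cc + d) > 0 && a / (a + b) > cc / (cc + d)
    data.table::data.table(
      node = j, n_node = a + b, n_hit = a, n_hit_bg = cc, p = p,
      enriched = p < p_threshold && over,
      log10_p_signed = if (over) -log10(p) else log10(p))
  })
  data.table::rbindlist(res)
}

enrichment_endpoints <- data.frame(
  assay_id = c("bla_agonist", "luc_agonist", "bla_antagonist",
               "luc_antagonist"),
  category = c("active_agonist", "active_agonist", "active_antagonist",
               "active_antagonist"),
  stringsAsFactors = FALSE)

#' Enrichment of active compounds per endpoint, with confound exclusion
#'
#' Runs [cluster_enrichment()] for one reporter endpoint (active agonists
#' for agonist-mode endpoints, active antagonists for antagonist-mode
#' endpoints). For antagonist endpoints, nodes that are also enriched in
#' cytotoxicity-demoted antagonist calls
#' (`inconclusive_antagonist_cytotox`) are flagged `confounded` and
#' excluded from the reported enriched set (`reported = enriched &
#' !confounded`).
#'
#' @param assignments node per compound, aligned with `library` order.
#' @param calls a [call_screen()] result.
#' @param library the [generate_library()] result.
#' @param assay one of the four reporter endpoints.
#' @param p_threshold enrichment threshold.
#' @return `data.table` per node with `enriched`, `confounded`, `reported`
#'   and `log10_p_signed`.
#' @export
assay_enrichment <- function(assignments, calls, library, assay,
                             p_threshold = 0.01) {
  cat <- enrichment_endpoints$category[
    enrichment_endpoints$assay_id == assay]
  if (length(cat) == 0) stop("unknown endpoint: ", assay, call. = FALSE)
  ids <- library$compounds$compound_id
  cc <- calls[assay_id == assay & sample_id == compound_id]
  outcome <- cc$outcome[match(ids, cc$sample_id)]
  enr <- cluster_enrichment(assignments, !is.na(outcome) & outcome == cat,
                            p_threshold = p_threshold)
  if (grepl("antagonist", assay)) {
    conf <- cluster_enrichment(
      assignments,
      !is.na(outcome) & outcome == "inconclusive_antagonist_cytotox",
      p_threshold = p_threshold)
    enr[, confounded := enriched & conf$enriched]
  } else {
    enr[, confounded := FALSE]
  }
  enr[, reported := enriched & !confounded]
  enr[]
}

#' Node-by-endpoint signed enrichment matrix
#'
#' Heatmap-ready matrix of signed log10 enrichment p-values (positive =
#' over-represented, negative = depleted) across the four reporter
#' endpoints.
#'
#' @inheritParams assay_enrichment
#' @return numeric matrix, nodes x endpoints, with an attribute
#'   `enrichment` holding the per-endpoint tables.
#' @export
enrichment_matrix <- function(assignments, calls, library,
                              p_threshold = 0.01) {
  tabs <- lapply(enrichment_endpoints$assay_id, function(a)
    assay_enrichment(assignments, calls, library, a, p_threshold))
  names(tabs) <- enrichment_endpoints$assay_id
  m <- vapply(tabs, function(t) t$log10_p_signed,
              numeric(nrow(tabs[[1]])))
  rownames(m) <- paste0("node", seq_len(nrow(m)))
  attr(m, "enrichment") <- tabs
  m
}
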