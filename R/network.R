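#' Network construction settings
#'
#' Bundles the options controlling co-occurrence network construction:
#' correlation estimator, edge-retention threshold, prevalence filter, and
#' the pseudocount / iteration count used by the compositional (SparCC)
#' estimator.
#'
#' @param estimator Correlation estimator: `"spearman"` (default; robust to
#'   compositional skew), `"pearson"`, or `"sparcc"` (log-ratio-variance
#'   compositional estimator, the default for first-order-neighbour graphs).
#' @param min_abs_corr Edges are retained when `|corr| >=` this threshold;
#'   in `[0, 1)`. Network topology is sensitive to this cutoff, so it is
#'   exposed rather than fixed.
#' @param min_prevalence Fraction of all samples in which a taxon must be
#'   nonzero to enter the network; in `(0, 1]` (0 keeps every taxon).
#' @param pseudocount Small positive value replacing zeros in log-ratio
#'   steps (sparcc) and in relative-change denominators.
#' @param sparcc_iterations Number of strongly-correlated-pair exclusion
#'   rounds in the sparcc basis-variance iteration.
#' @param seed Optional integer seed for stochastic estimators (none of the
#'   built-in estimators draw random numbers; kept for extensions).
#' @return A `network_config` list.
#' @export
network_config <- function(estimator = c("spearman", "pearson", "sparcc"),
                           min_abs_corr = 0.3,
                           min_prevalence = 0,
                           pseudocount = 1e-6,
                           sparcc_iterations = 10,
                           seed = NULL) {
  estimator <- match.arg(estimator)
  stopifnot(min_abs_corr >= 0, min_abs_corr < 1,
            min_prevalence >= 0, min_prevalence <= 1,
            pseudocount > 0, sparcc_iterations >= 1)
  structure(list(estimator = estimator, min_abs_corr = min_abs_corr,
                 min_prevalence = min_prevalence, pseudocount = pseudocount,
                 sparcc_iterations = as.integer(sparcc_iterations),
                 seed = seed),
            class = "network_config")
}

#' Prevalence-filter the taxa of a study
#'
#' Retains taxa that are present (abundance > 0) in at least
#' `cfg$min_prevalence` of all samples, preserving taxon order. Low-prevalence
#' taxa destabilise correlation estimates, so they are removed before network
#' construction.
#'
#' @param study An `sna_study`.
#' @param cfg A [network_config()].
#' @return The filtered `sna_study`.
#' @export
filter_taxa <- function(study, cfg = network_config()) {
  stopifnot(inherits(study, "sna_study"))
  prev <- rowMeans(study$abundance > 0)
  keep <- prev >= cfg$min_prevalence
  if (sum(keep) < 3L) {
    abort(paste0("prevalence filter leaves ", sum(keep),
                 " taxa; a network needs at least 3"))
  }
  out <- study
  out$taxa <- study$taxa[keep]
  out$abundance <- study$abundance[keep, , drop = FALSE]
  out
}

#' Estimate pairwise taxon correlations within one cohort
#'
#' Computes the symmetric, unit-diagonal correlation matrix among taxa from
#' the relative abundances of one cohort's samples, using the estimator named
#' in `cfg`. Zero-variance taxa cannot be correlated; their off-diagonal
#' entries are set to 0 and recorded in the `"zero_variance"` attribute
#' rather than propagated as `NA`.
#'
#' @param study An `sna_study`, typically restricted to one cohort via
#'   [cohort_subset()] (a full study is correlated as-is).
#' @param cfg A [network_config()].
#' @return An n-by-n correlation matrix with taxa dimnames, values in
#'   `[-1, 1]`, attribute `zero_variance` naming flagged taxa.
#' @export
estimate_correlations <- function(study, cfg = network_config()) {
  stopifnot(inherits(study, "sna_study"))
  x <- study$abundance
  if (ncol(x) < 3L) abort("need at least 3 samples to estimate correlations")
  zero_var <- apply(x, 1L, function(r) var(r) == 0 || !is.finite(var(r)))
  corr <- switch(cfg$estimator,
    spearman = suppressWarnings(cor(t(x), method = "spearman")),
    pearson  = suppressWarnings(cor(t(x), method = "pearson")),
    sparcc   = sparcc_correlations(x, pseudocount = cfg$pseudocount,
                                   iterations = cfg$sparcc_iterations)
  )
  corr[!is.finite(corr)] <- 0
  if (any(zero_var)) {
    corr[zero_var, ] <- 0
    corr[, zero_var] <- 0
  }
  corr <- (corr + t(corr)) / 2
  corr[corr > 1] <- 1
  corr[corr < -1] <- -1
  diag(corr) <- 1
  dimnames(corr) <- list(study$taxa, study$taxa)
  attr(corr, "zero_variance") <- study$taxa[zero_var]
  corr
}

#' Build a signed weighted co-occurrence network
#'
#' Thresholds a correlation matrix into a network: an edge `{i, j}` is
#' retained when `|corr_ij| >= cfg$min_abs_corr`. Edge weights `W` store
#' correlation magnitudes with a unit diagonal — `W` doubles as the network's
#' stiffness matrix, and the unit diagonal keeps it diagonally dominant
#' enough to invert in typical instances — while edge signs are kept in a
#' separate `sign` matrix for positive/negative-edge analyses.
#'
#' @param corr Symmetric correlation matrix with unit diagonal and taxa
#'   dimnames.
#' @param cfg A [network_config()].
#' @return An `sna_network`: list with `taxa`, `W` (magnitudes, diagonal 1),
#'   `sign` (-1/0/+1), `A` (0/1 adjacency, diagonal 0), `estimator_tag`.
#' @export
build_network <- function(corr, cfg = network_config()) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (max(abs(corr - t(corr))) > 1e-8) abort("correlation matrix not symmetric")
  taxa <- rownames(corr) %||% paste0("t", seq_len(nrow(corr)))
  n <- nrow(corr)
  A <- (abs(corr) >= cfg$min_abs_corr) * 1
  diag(A) <- 0
  sgn <- sign(corr) * A
  W <- abs(corr) * A
  diag(W) <- 1
  dimnames(W) <- dimnames(A) <- dimnames(sgn) <- list(taxa, taxa)
  structure(list(taxa = taxa, W = W, sign = sgn, A = A,
                 estimator_tag = cfg$estimator),
            class = "sna_network")
}

#' Positive-to-negative edge ratio
#'
#' The P/N ratio — the count of positive (cooperative) edges divided by the
#' count of negative (competitive) edges — summarises the balance of species
#' interactions in a (sub)network. With positive edges but no negative ones
#' the ratio is `Inf` (serialised as `"-"` by [format_pn()]); with no edges
#' at all it is `NaN`.
#'
#' @param net An `sna_network`.
#' @param edge_subset Optional two-column matrix or data frame of taxon-name
#'   pairs restricting the count to those edges (must exist in `net`).
#' @return A double: the ratio, `Inf` (positive-only) or `NaN` (no edges),
#'   with attributes `n_pos` and `n_neg`.
#' @export
pn_ratio <- function(net, edge_subset = NULL) {
  stopifnot(inherits(net, "sna_network"))
  s <- net$sign
  if (!is.null(edge_subset)) {
    es <- as.matrix(edge_subset)
    i <- match(es[, 1L], net$taxa)
    j <- match(es[, 2L], net$taxa)
    if (anyNA(i) || anyNA(j)) abort("edge_subset names unknown taxa")
    if (any(net$A[cbind(i, j)] == 0)) abort("edge_subset contains non-edges")
    vals <- s[cbind(i, j)]
  } else {
    vals <- s[upper.tri(s)]
  }
  n_pos <- sum(vals > 0)
  n_neg <- sum(vals < 0)
  out <- if (n_pos + n_neg == 0L) NaN else n_pos / n_neg
  structure(out, n_pos = n_pos, n_neg = n_neg)
}

#' Format a P/N ratio for reporting
#'
#' Positive-only ratios print as `"-"` (no negative edges exist); empty edge
#' sets print as `"NA"`.
#'
#' @param x Value returned by [pn_ratio()] (or any double).
#' @param digits Significant digits for finite ratios.
#' @return A character scalar.
#' @export
format_pn <- function(x, digits = 4) {
  x <- as.numeric(x)
  if (is.nan(x)) return("NA")
  if (is.infinite(x)) return("-")
  as.character(signif(x, digits))
}

#' @export
print.sna_network <- function(x, ...) {
  ne <- sum(x$A[upper.tri(x$A)])
  np <- sum(x$sign[upper.tri(x$sign)] > 0)
  cat("<sna_network> ", length(x$taxa), " taxa, ", ne, " edges (",
      np, " positive, ", ne - np, " negative), estimator: ",
      x$estimator_tag, "\n", sep = "")
  invisible(x)
}

#' Tidy a network into an edge table
#'
#' @param x An `sna_network`.
#' @param ... Unused.
#' @return A tibble with one row per undirected edge (`taxon_i < taxon_j` in
#'   taxon order): columns `taxon_i`, `taxon_j`, `weight`, `sign`.
#' @method tidy sna_network
#' @export
tidy.sna_network <- function(x, ...) {
  idx <- which(upper.tri(x$A) & x$A == 1, arr.ind = TRUE)
  tibble(taxon_i = x$taxa[idx[, 1L]],
         taxon_j = x$taxa[idx[, 2L]],
         weight = x$W[idx],
         sign = as.integer(x$sign[idx]))
}

#' @method glance sna_network
#' @export
glance.sna_network <- function(x, ...) {
  ut <- upper.tri(x$A)
  ne <- sum(x$A[ut])
  tibble(n_taxa = length(x$taxa),
         n_edges = ne,
         n_pos = sum(x$sign[ut] > 0),
         n_neg = sum(x$sign[ut] < 0),
         pn_ratio = as.numeric(pn_ratio(x)),
         density = ne / choose(length(x$taxa), 2))
}
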