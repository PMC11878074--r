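#' Specification for a synthetic two-cohort study
#'
#' Describes a logistic-normal compositional model with a block correlation
#' backbone and a planted relationship alteration: samples in both cohorts
#' share the same log-scale mean vector (so marginal abundances match and
#' any cohort difference lives purely in the association structure), cohort
#' A uses the backbone correlation matrix, and cohort B uses a copy whose
#' entries among the planted taxa are rewired.
#'
#' Defaults emulate a modest 16S-style comparison: 40 taxa in 30 + 30
#' samples, four correlated blocks of five taxa (within-block correlations
#' 0.7, 0.6, 0.5 and 0.4) on an otherwise independent background, a
#' log-abundance gradient across taxa, 10% extra zeros, and a five-taxon
#' sign-flip alteration in the first block.
#'
#' @param n_taxa Number of taxa.
#' @param n_samples_a,n_samples_b Cohort sample sizes.
#' @param blocks List of `c(size, rho)` pairs placed consecutively along the
#'   diagonal of the backbone correlation matrix; remaining taxa are
#'   uncorrelated.
#' @param planted_subset Integer taxon indices whose cohort-B correlations
#'   are rewired; `integer(0)` plants nothing (exchangeable cohorts).
#' @param rewire_mode `"sign_flip"` (negate the planted within-subset
#'   correlations), `"decorrelate"` (zero them), or `"strengthen"` (push
#'   their magnitudes to at least 0.9).
#' @param mean_logabund Log-scale mean vector (length `n_taxa`); default an
#'   even gradient from 2 to -2.
#' @param sd_logabund Log-scale standard deviation (scalar or length
#'   `n_taxa`).
#' @param zero_inflation Probability of forcing an entry to zero before
#'   renormalisation, in `[0, 1)`.
#' @param seed Integer seed used by [generate_study()].
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_taxa = 40,
                           n_samples_a = 30, n_samples_b = 30,
                           blocks = list(c(5, 0.7), c(5, 0.6),
                                         c(5, 0.5), c(5, 0.4)),
                           planted_subset = 1:5,
                           rewire_mode = c("sign_flip", "decorrelate",
                                           "strengthen"),
                           mean_logabund = NULL,
                           sd_logabund = 1,
                           zero_inflation = 0.1,
                           seed = 1L) {
  rewire_mode <- match.arg(rewire_mode)
  stopifnot(n_taxa >= 3, n_samples_a >= 2, n_samples_b >= 2,
            zero_inflation >= 0, zero_inflation < 1)
  if (sum(vapply(blocks, `[`, 0, 1)) > n_taxa) {
    abort("block sizes exceed n_taxa")
  }
  planted_subset <- as.integer(planted_subset)
  if (length(planted_subset) &&
      (min(planted_subset) < 1L || max(planted_subset) > n_taxa)) {
    abort("planted_subset out of range")
  }
  mean_logabund <- mean_logabund %||% seq(2, -2, length.out = n_taxa)
  stopifnot(length(mean_logabund) == n_taxa)
  structure(list(n_taxa = n_taxa, n_samples_a = n_samples_a,
                 n_samples_b = n_samples_b, blocks = blocks,
                 planted_subset = planted_subset,
                 rewire_mode = rewire_mode,
                 mean_logabund = mean_logabund,
                 sd_logabund = rep_len(sd_logabund, n_taxa),
                 zero_inflation = zero_inflation,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Block-diagonal backbone correlation matrix from the spec's block list.
backbone_matrix <- function(spec) {
  R <- diag(spec$n_taxa)
  at <- 1L
  for (b in spec$blocks) {
    size <- as.integer(b[1L])
    rho <- b[2L]
    idx <- at:(at + size - 1L)
    R[idx, idx] <- rho
    at <- at + size
  }
  diag(R) <- 1
  R
}

rewire_matrix <- function(R, planted, mode) {
  if (length(planted) < 2L) return(R)
  sub <- R[planted, planted]
  off <- !diag(nrow(sub))
  sub[off] <- switch(mode,
    sign_flip = -sub[off],
    decorrelate = 0,
    strengthen = {
      v <- sub[off]
      s <- ifelse(v == 0, 1, sign(v))
      s * pmax(abs(v), 0.9)
    })
  R[planted, planted] <- sub
  R
}

# Validate / repair positive semi-definiteness; repair is logged, never
# silent (sign-flipping an equicorrelated block routinely breaks PSD).
ensure_psd <- function(R, label) {
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= -1e-10) return(R)
  warn(paste0(label, " correlation matrix not positive semi-definite ",
              "(min eigenvalue ", signif(min(ev), 3),
              "); applying nearest-PSD repair"))
  out <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
  dimnames(out) <- dimnames(R)
  out
}

#' Generate a synthetic two-cohort study with known ground truth
#'
#' Draws both cohorts from the logistic-normal model of a
#' [synthetic_spec()]: multivariate normal on the log scale with
#' cohort-specific correlation (backbone for A, rewired for B) and identical
#' means, exponentiated, zero-inflated by an independent Bernoulli mask, and
#' renormalised to per-sample proportions. Deterministic given the spec's
#' seed.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Optional seed overriding `spec$seed`.
#' @return A list with `study` (an `sna_study`; cohort labels `"A"`/`"B"`)
#'   and `truth` (a `sna_ground_truth`: `planted` taxon names, `corr_a`,
#'   `corr_b`, the spec).
#' @export
generate_study <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  seed <- seed %||% spec$seed
  n <- spec$n_taxa
  taxa <- sprintf("taxon_%02d", seq_len(n))

  R_a <- ensure_psd(backbone_matrix(spec), "backbone")
  R_b <- ensure_psd(rewire_matrix(R_a, spec$planted_subset,
                                  spec$rewire_mode), "rewired")

  D <- diag(spec$sd_logabund, n)
  sigma_a <- D %*% R_a %*% D
  sigma_b <- D %*% R_b %*% D

  mat <- withr::with_seed(seed, {
    za <- MASS::mvrnorm(spec$n_samples_a, mu = spec$mean_logabund,
                        Sigma = sigma_a)
    zb <- MASS::mvrnorm(spec$n_samples_b, mu = spec$mean_logabund,
                        Sigma = sigma_b)
    ab <- t(rbind(za, zb))          # taxa x samples, log scale
    ab <- exp(ab)
    if (spec$zero_inflation > 0) {
      mask <- matrix(runif(length(ab)) < spec$zero_inflation,
                     nrow = nrow(ab))
      # never zero out an entire sample
      for (j in which(colSums(!mask) == 0)) mask[sample.int(n, 1L), j] <- FALSE
      ab[mask] <- 0
    }
    ab
  })
  samples <- sprintf("sample_%03d", seq_len(ncol(mat)))
  dimnames(mat) <- list(taxa, samples)
  cohort_lab <- rep(c("A", "B"), c(spec$n_samples_a, spec$n_samples_b))
  md <- data.frame(sample = samples, cohort = cohort_lab)
  study <- suppressWarnings(
    sna_study(mat, md, cohort_column = "cohort", ref_label = "A"))

  truth <- structure(
    list(planted = taxa[spec$planted_subset],
         corr_a = `dimnames<-`(R_a, list(taxa, taxa)),
         corr_b = `dimnames<-`(R_b, list(taxa, taxa)),
         spec = spec),
    class = "sna_ground_truth")
  list(study = study, truth = truth)
}

#' Ground-truth labels of a synthetic study
#'
#' @param truth An `sna_ground_truth` from [generate_study()].
#' @return A tibble with columns `taxon`, `label` in
#'   `{"planted", "unplanted"}`.
#' @export
truth_labels <- function(truth) {
  stopifnot(inherits(truth, "sna_ground_truth"))
  taxa <- rownames(truth$corr_a)
  tibble(taxon = taxa,
         label = ifelse(taxa %in% truth$planted, "planted", "unplanted"))
}
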