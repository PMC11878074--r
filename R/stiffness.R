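#' Construct a network directly from matrices
#'
#' Low-level constructor for toy instances and tests: builds an
#' `sna_network` from an explicit weight matrix (and optionally sign and
#' adjacency matrices) without thresholding a correlation matrix.
#'
#' @param W Symmetric numeric weight matrix (taxa dimnames optional).
#' @param sign Optional symmetric sign matrix in `{-1, 0, 1}`; defaults to
#'   `sign(W)` off the diagonal.
#' @param A Optional 0/1 adjacency; defaults to `W != 0` off the diagonal.
#' @param estimator_tag Provenance string.
#' @return An `sna_network`.
#' @export
sna_network_from_w <- function(W, sign = NULL, A = NULL,
                               estimator_tag = "manual") {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (max(abs(W - t(W))) > 1e-10) abort("W must be symmetric")
  n <- nrow(W)
  taxa <- rownames(W) %||% paste0("t", seq_len(n))
  if (is.null(A)) {
    A <- (W != 0) * 1
    diag(A) <- 0
  }
  if (is.null(sign)) sign <- base::sign(W) * A
  dimnames(W) <- dimnames(A) <- dimnames(sign) <- list(taxa, taxa)
  structure(list(taxa = taxa, W = W, sign = sign, A = A,
                 estimator_tag = estimator_tag),
            class = "sna_network")
}

# Effective stiffness matrix: off-diagonal weights masked by the adjacency,
# diagonal kept from W (unit for thresholded networks). `unweighted` swaps in
# the hollow 0/1 adjacency, the regime in which the degree vector applied as
# force produces unit displacements.
stiffness_matrix <- function(net, unweighted = FALSE) {
  if (unweighted) return(net$A)
  K <- net$W * net$A
  diag(K) <- diag(net$W)
  K
}

#' Force on network nodes from an observed displacement
#'
#' Treating the network weight matrix as a stiffness matrix `K`, the force
#' that produces an observed node displacement `d` (here: the change in mean
#' relative abundance between cohorts) is `f = K d`.
#'
#' @param net An `sna_network`.
#' @param d Numeric displacement vector, one entry per taxon.
#' @param unweighted Use the 0/1 adjacency as the stiffness matrix instead of
#'   the weights.
#' @return Numeric force vector (in weight-times-attribute units).
#' @export
compute_force <- function(net, d, unweighted = FALSE) {
  stopifnot(inherits(net, "sna_network"))
  if (length(d) != length(net$taxa)) {
    abort(paste0("displacement length ", length(d), " != ",
                 length(net$taxa), " taxa"))
  }
  drop(stiffness_matrix(net, unweighted) %*% d)
}

#' Displacement of network nodes under a known force
#'
#' Solves the linear stiffness system `K d = f` for the node displacements.
#' When `K` is singular or its condition number exceeds `cond_cap`, the
#' minimum-norm least-squares solution (Moore-Penrose pseudoinverse) is
#' returned instead and the result is flagged via the `"regularized"`
#' attribute — never silently.
#'
#' @param net An `sna_network`.
#' @param f Numeric force vector.
#' @param cond_cap Condition-number cap above which the pseudoinverse is
#'   used; default `1e12`.
#' @param unweighted Use the 0/1 adjacency as the stiffness matrix.
#' @return Numeric displacement vector with attribute `regularized`
#'   (`TRUE`/`FALSE`).
#' @export
compute_displacement <- function(net, f, cond_cap = 1e12,
                                 unweighted = FALSE) {
  stopifnot(inherits(net, "sna_network"))
  if (length(f) != length(net$taxa)) {
    abort(paste0("force length ", length(f), " != ",
                 length(net$taxa), " taxa"))
  }
  K <- stiffness_matrix(net, unweighted)
  kap <- tryCatch(kappa(K, exact = TRUE), error = function(e) Inf)
  regularized <- !is.finite(kap) || kap > cond_cap
  d <- if (regularized) {
    drop(MASS::ginv(K) %*% f)
  } else {
    sol <- tryCatch(solve(K, f), error = function(e) NULL)
    if (is.null(sol)) {
      regularized <- TRUE
      drop(MASS::ginv(K) %*% f)
    } else drop(sol)
  }
  structure(d, regularized = regularized)
}

#' Per-node stiffness scale between two attribute states
#'
#' Finds the diagonal scaling `diag(s)` such that `diag(s) W y = x`, giving
#' each node the factor by which its weighted neighbourhood of the cause
#' state `y` must be scaled to produce the effect state `x`:
#' `s_i = x_i / sum_j w_ij y_j`. Entries whose denominator is numerically
#' zero (|.| < 1e-12) are undefined and returned as `NA`, never as 0.
#'
#' @param net An `sna_network`.
#' @param x Effect-state attribute vector (condition cohort mean abundance).
#' @param y Cause-state attribute vector (reference cohort mean abundance).
#' @return Numeric vector `s` with `NA` at undefined entries; the identity
#'   `diag(s) W y = x` holds on defined entries.
#' @export
compute_stiffness_scale <- function(net, x, y) {
  stopifnot(inherits(net, "sna_network"))
  n <- length(net$taxa)
  if (length(x) != n || length(y) != n) abort("attribute length != n taxa")
  K <- stiffness_matrix(net)
  denom <- drop(K %*% y)
  s <- ifelse(abs(denom) < 1e-12, NA_real_, x / denom)
  s
}

#' Relative-change perturbation matrix between two states
#'
#' For the attribute change `dx = x_b - x_a` and per-node relative change
#' `r_i = dx_i / max(x_a_i, pseudocount)`, the perturbation (correlation)
#' matrix `G_ij = |r_i / r_j|` captures the influence of node `j` on node
#' `i`. Columns with `|r_j| < 1e-12` are undefined and masked.
#'
#' @param x_a,x_b Nonnegative attribute vectors at the two states (reference
#'   and condition cohort mean abundances).
#' @param pseudocount Floor applied to the baseline `x_a` denominator so
#'   zero-abundance baselines yield finite relative changes.
#' @return An `sna_perturbation`: list with `G` (nonnegative matrix, `NA`
#'   where undefined) and `defined` (logical mask).
#' @export
compute_perturbation_matrix <- function(x_a, x_b, pseudocount = 1e-6) {
  stopifnot(length(x_a) == length(x_b), pseudocount > 0)
  if (any(x_a < 0) || any(x_b < 0)) abort("attribute values must be >= 0")
  r <- (x_b - x_a) / pmax(x_a, pseudocount)
  ok <- abs(r) > 1e-12
  n <- length(r)
  G <- matrix(NA_real_, n, n)
  defined <- outer(rep(TRUE, n), ok, "&")
  G[defined] <- abs(outer(r, r, "/"))[defined]
  nm <- names(x_a) %||% names(x_b)
  if (!is.null(nm)) dimnames(G) <- dimnames(defined) <- list(nm, nm)
  structure(list(G = G, defined = defined), class = "sna_perturbation")
}

#' Node impact: neighbourhood response to a node's perturbation
#'
#' `I_i = sum_j A_ij G_ji`, the summed relative response of node `i`'s
#' first-order neighbours to a perturbation of `i` (note the transposed
#' perturbation matrix). Undefined `G` entries are excluded from the sum;
#' nodes with no defined neighbour term (isolated nodes included) are
#' returned as `NA`.
#'
#' @param net An `sna_network`.
#' @param P An `sna_perturbation` from [compute_perturbation_matrix()].
#' @return Numeric impact vector with `NA` at undefined entries.
#' @export
compute_impact <- function(net, P) {
  stopifnot(inherits(net, "sna_network"), inherits(P, "sna_perturbation"))
  n <- length(net$taxa)
  if (nrow(P$G) != n) abort("perturbation matrix size != n taxa")
  Gt <- t(P$G)
  def <- t(P$defined)
  term <- net$A * Gt
  term[net$A == 0 | !def] <- NA_real_
  vapply(seq_len(n), function(i) {
    v <- term[i, ]
    if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
  }, numeric(1))
}

#' Node stability: inverse response to neighbour perturbations
#'
#' `S_i = 1 / sum_j A_ij G_ij`, the reciprocal of node `i`'s summed relative
#' response to perturbations of its first-order neighbours. Values near 0
#' mark nodes susceptible to disturbance; values near 1 mark stable nodes.
#' Values are reported raw — when a value exceeds 1 a note is emitted, not a
#' clip. Zero denominators and nodes with no defined neighbour term give
#' `NA`.
#'
#' @inheritParams compute_impact
#' @return Numeric stability vector with `NA` at undefined entries.
#' @export
compute_stability <- function(net, P) {
  stopifnot(inherits(net, "sna_network"), inherits(P, "sna_perturbation"))
  n <- length(net$taxa)
  if (nrow(P$G) != n) abort("perturbation matrix size != n taxa")
  term <- net$A * P$G
  term[net$A == 0 | !P$defined] <- NA_real_
  S <- vapply(seq_len(n), function(i) {
    v <- term[i, ]
    if (all(is.na(v))) return(NA_real_)
    den <- sum(v, na.rm = TRUE)
    if (den == 0) NA_real_ else 1 / den
  }, numeric(1))
  over <- sum(S > 1, na.rm = TRUE)
  if (over > 0) {
    inform(paste0("stability exceeds 1 for ", over,
                  " taxa (reported raw, not clipped)"))
  }
  S
}

#' Full per-taxon stiffness profile for a cohort comparison
#'
#' Assembles the five stiffness parameters for a network and a pair of
#' attribute states: force from the observed displacement
#' `d_obs = x_b - x_a`; displacement from solving the stiffness system for
#' that force; stiffness scale mapping the reference state onto the
#' condition state; and impact and stability from the relative-change
#' perturbation matrix. Undefined entries are `NA`, never silent zeros.
#'
#' @param net An `sna_network`.
#' @param x_a,x_b Attribute vectors (per-taxon mean relative abundance in
#'   the reference and condition cohorts). May be given as a tibble from
#'   [cohort_means()] via `attr`.
#' @param attr Optional tibble with columns `taxon`, `x_a`, `x_b` (as from
#'   [cohort_means()]); overrides `x_a`/`x_b`.
#' @param pseudocount Baseline floor for relative changes.
#' @param cond_cap Condition-number cap for the displacement solve.
#' @return An `sna_profile` tibble with columns `taxon`, `force`,
#'   `displacement`, `stiffness_scale`, `impact`, `stability`; attribute
#'   `regularized` records whether the displacement solve fell back to the
#'   pseudoinverse.
#' @export
compute_profile <- function(net, x_a = NULL, x_b = NULL, attr = NULL,
                            pseudocount = 1e-6, cond_cap = 1e12) {
  stopifnot(inherits(net, "sna_network"))
  if (!is.null(attr)) {
    if (!all(c("taxon", "x_a", "x_b") %in% names(attr))) {
      abort("attr needs columns taxon, x_a, x_b")
    }
    m <- match(net$taxa, attr$taxon)
    if (anyNA(m)) abort("attr missing some network taxa")
    x_a <- attr$x_a[m]
    x_b <- attr$x_b[m]
  }
  n <- length(net$taxa)
  if (length(x_a) != n || length(x_b) != n) abort("attribute length != n taxa")

  d_obs <- x_b - x_a
  f <- compute_force(net, d_obs)
  d <- compute_displacement(net, f, cond_cap = cond_cap)
  s <- compute_stiffness_scale(net, x = x_b, y = x_a)
  P <- compute_perturbation_matrix(x_a, x_b, pseudocount = pseudocount)
  impact <- compute_impact(net, P)
  stability <- compute_stability(net, P)

  out <- tibble(taxon = net$taxa,
                force = unname(f),
                displacement = unname(as.numeric(d)),
                stiffness_scale = unname(s),
                impact = unname(impact),
                stability = unname(stability))
  class(out) <- c("sna_profile", class(out))
  attr(out, "regularized") <- isTRUE(base::attr(d, "regularized"))
  attr(out, "x_a") <- x_a
  attr(out, "x_b") <- x_b
  out
}

#' Tidy a stiffness profile into long form
#'
#' @param x An `sna_profile`.
#' @param ... Unused.
#' @return A tibble with columns `taxon`, `parameter`, `value`.
#' @method tidy sna_profile
#' @export
tidy.sna_profile <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -"taxon",
                      names_to = "parameter", values_to = "value")
}

#' Summarise a stiffness profile
#'
#' One row per parameter with the mean, minimum and maximum over taxa with
#' defined values, matching the mean-[min, max] reporting convention.
#'
#' @param x An `sna_profile`.
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `mean`, `min`, `max`,
#'   `n_defined`, `n_undefined`.
#' @method glance sna_profile
#' @export
glance.sna_profile <- function(x, ...) {
  tidy(x) |>
    group_by(.data$parameter) |>
    summarise(mean = mean(.data$value, na.rm = TRUE),
              min = suppressWarnings(min(.data$value, na.rm = TRUE)),
              max = suppressWarnings(max(.data$value, na.rm = TRUE)),
              n_defined = sum(!is.na(.data$value)),
              n_undefined = sum(is.na(.data$value)),
              .groups = "drop")
}
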