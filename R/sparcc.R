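# Compositional (SparCC-style) correlation estimation.
#
# The estimator works on log-ratio variances, which are invariant to the
# per-sample total and therefore free of the closure-induced negative bias of
# naive correlations on proportions. For taxa i, j with components x_i, x_j:
#
#   T_ij = var(log(x_i / x_j)) = w_i + w_j - 2 * rho_ij * sqrt(w_i * w_j)
#
# where w_i is the (unobservable) basis variance of taxon i. Under the
# sparsity assumption that correlations sum to ~0, the row sums
# t_i = sum_j T_ij give the linear system t = [(n-2) I + J] w, solved for the
# basis variances; rho then follows from the display above. Strongly
# correlated pairs violate the sparsity assumption, so the most correlated
# pair is excluded from the row sums and the system re-solved for a fixed
# number of rounds. This is a deterministic point estimate (zeros replaced by
# a pseudocount; no Dirichlet resampling).

sparcc_correlations <- function(x, pseudocount = 1e-6, iterations = 10,
                                exclusion_threshold = 0.1) {
  n <- nrow(x)
  if (n < 4L) abort("sparcc needs at least 4 taxa")
  lx <- log(pmax(x, pseudocount))
  # T_ij = var over samples of log(x_i) - log(x_j)
  v <- apply(lx, 1L, var)
  cv <- cov(t(lx))
  Tmat <- outer(v, v, "+") - 2 * cv
  diag(Tmat) <- 0

  excluded <- matrix(FALSE, n, n)
  rho <- NULL
  for (iter in seq_len(iterations)) {
    M <- matrix(1, n, n)
    diag(M) <- n - 2
    # excluding pair (i,j) removes T_ij from t_i and drops w_j's contribution
    if (any(excluded)) {
      for (i in seq_len(n)) {
        ex <- which(excluded[i, ])
        if (length(ex)) {
          M[i, i] <- M[i, i] - length(ex)
          M[i, ex] <- M[i, ex] - 1
        }
      }
    }
    tvec <- rowSums(Tmat * !excluded)
    w <- tryCatch(solve(M, tvec), error = function(e) rep(NA_real_, n))
    if (anyNA(w)) break
    w <- pmax(w, .Machine$double.eps)
    denom <- 2 * sqrt(outer(w, w))
    rho <- (outer(w, w, "+") - Tmat) / denom
    rho[rho > 1] <- 1
    rho[rho < -1] <- -1
    diag(rho) <- 1
    # exclude the currently strongest not-yet-excluded pair, if any remains
    cand <- abs(rho)
    cand[excluded | !upper.tri(cand)] <- 0
    mx <- max(cand)
    if (mx < exclusion_threshold) break
    idx <- which(cand == mx, arr.ind = TRUE)[1L, , drop = TRUE]
    # never isolate a taxon: each needs >= 2 partners left in its row sum
    if (sum(!excluded[idx[1L], -idx[1L]]) <= 2L ||
        sum(!excluded[idx[2L], -idx[2L]]) <= 2L) break
    excluded[idx[1L], idx[2L]] <- excluded[idx[2L], idx[1L]] <- TRUE
  }
  if (is.null(rho)) rho <- diag(n)
  rho
}
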