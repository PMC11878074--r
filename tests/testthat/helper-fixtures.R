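# Shared fixtures: all built in code, deterministic under explicit seeds.

# Small counts study: 3 taxa x 4 samples, 2 + 2 cohorts.
toy_counts <- function() {
  data.frame(taxon = c("t1", "t2", "t3"),
             s1 = c(5, 3, 2), s2 = c(1, 1, 2),
             s3 = c(4, 4, 2), s4 = c(0, 6, 4))
}

toy_metadata <- function() {
  data.frame(sample = paste0("s", 1:4),
             group = c("HC", "HC", "ASD", "ASD"))
}

toy_study <- function() {
  sna_study(toy_counts(), toy_metadata(),
            cohort_column = "group", ref_label = "HC")
}

# Random signed network on n nodes: each pair gets an edge with prob p_edge,
# weight in (0.3, 1), sign +/-1.
random_signed_network <- function(n, p_edge = 0.4, seed = 1) {
  withr::with_seed(seed, {
    W <- matrix(0, n, n)
    sgn <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (runif(1) < p_edge) {
          w <- runif(1, 0.3, 1)
          s <- sample(c(-1, 1), 1)
          W[i, j] <- W[j, i] <- w
          sgn[i, j] <- sgn[j, i] <- s
        }
      }
    }
    A <- (W > 0) * 1
    diag(W) <- 1
    sna_network_from_w(W, sign = sgn, A = A)
  })
}

# Random positive x_a, x_b attribute pair.
random_attributes <- function(n, seed = 1) {
  withr::with_seed(seed, list(x_a = runif(n, 0.01, 1),
                              x_b = runif(n, 0.01, 1)))
}

# Independent brute-force oracles (deliberately naive double loops).
oracle_impact <- function(A, G) {
  n <- nrow(A)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    acc <- 0
    seen <- FALSE
    for (j in seq_len(n)) {
      if (A[i, j] == 1 && !is.na(G[j, i])) {
        acc <- acc + G[j, i]
        seen <- TRUE
      }
    }
    if (seen) out[i] <- acc
  }
  out
}

oracle_stability <- function(A, G) {
  n <- nrow(A)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    acc <- 0
    seen <- FALSE
    for (j in seq_len(n)) {
      if (A[i, j] == 1 && !is.na(G[i, j])) {
        acc <- acc + G[i, j]
        seen <- TRUE
      }
    }
    if (seen && acc != 0) out[i] <- 1 / acc
  }
  out
}

oracle_pn <- function(net) {
  np <- 0; nn <- 0
  n <- length(net$taxa)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (net$sign[i, j] > 0) np <- np + 1
      if (net$sign[i, j] < 0) nn <- nn + 1
    }
  }
  c(pos = np, neg = nn)
}

# Naive union-find over positive edges among a taxon subset.
oracle_positive_components <- function(net, taxa_subset) {
  idx <- match(taxa_subset, net$taxa)
  parent <- seq_along(idx)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_along(idx)) {
    for (b in seq_along(idx)) {
      if (a < b && net$sign[idx[a], idx[b]] > 0) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  roots <- vapply(seq_along(idx), find, 0L)
  split(taxa_subset, roots)
}
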