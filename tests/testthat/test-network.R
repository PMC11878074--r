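test_that("prevalence filter matches a direct nonzero-fraction count", {
  withr::with_seed(7, {
    mat <- matrix(rexp(10 * 10), 10, 10,
                  dimnames = list(paste0("t", 1:10), paste0("s", 1:10)))
    mat[matrix(runif(100) < 0.5, 10, 10)] <- 0
    mat[1, ] <- pmax(mat[1, ], 0.1)  # keep every sample nonempty
  })
  md <- data.frame(sample = paste0("s", 1:10),
                   cohort = rep(c("A", "B"), each = 5))
  st <- suppressWarnings(sna_study(mat, md, "cohort", "A"))

  cfg <- network_config(min_prevalence = 0.5)
  kept <- filter_taxa(st, cfg)$taxa
  expected <- st$taxa[rowMeans(st$abundance > 0) >= 0.5]
  expect_equal(kept, expected)

  # prevalence 0 is the identity on the taxa set
  expect_equal(filter_taxa(st, network_config(min_prevalence = 0))$taxa,
               st$taxa)

  # a taxon present in 1 of 10 samples is dropped at 0.2
  st1 <- st
  st1$abundance[3, ] <- 0
  st1$abundance[3, 1] <- 0.05
  expect_false("t3" %in% filter_taxa(st1,
                                     network_config(min_prevalence = 0.2))$taxa)

  expect_error(filter_taxa(st, network_config(min_prevalence = 1)),
               "at least 3")
})

test_that("spearman correlations respect rank agreement and unit diagonal", {
  mat <- rbind(t1 = c(1, 2, 3, 4, 5),
               t2 = c(2, 4, 6, 8, 10),   # same rank order as t1
               t3 = c(5, 4, 3, 2, 1))
  mat <- sweep(mat, 2, colSums(mat), "/")
  colnames(mat) <- paste0("s", 1:5)
  md <- data.frame(sample = paste0("s", 1:5),
                   cohort = c("A", "A", "A", "B", "B"))
  st <- sna_study(mat, md, "cohort", "A")
  corr <- estimate_correlations(st, network_config(estimator = "spearman"))
  expect_equal(unname(diag(corr)), rep(1, 3))
  expect_equal(corr["t1", "t2"], 1)
  expect_equal(corr["t1", "t3"], -1)
})

test_that("zero-variance taxa get zero correlations and a flag, not NaN", {
  mat <- rbind(t1 = c(0.2, 0.2, 0.2, 0.2),
               t2 = c(0.1, 0.3, 0.2, 0.4),
               t3 = c(0.7, 0.5, 0.6, 0.4))
  colnames(mat) <- paste0("s", 1:4)
  md <- data.frame(sample = paste0("s", 1:4),
                   cohort = c("A", "A", "B", "B"))
  st <- sna_study(mat, md, "cohort", "A")
  # t1 constant across all samples (proportions unchanged by normalisation)
  corr <- estimate_correlations(st, network_config(estimator = "pearson"))
  expect_false(anyNA(corr))
  expect_equal(unname(corr["t1", c("t2", "t3")]), c(0, 0))
  expect_true("t1" %in% attr(corr, "zero_variance"))
})

test_that("correlations are invariant to sample order within a cohort", {
  gen <- suppressWarnings(
    generate_study(synthetic_spec(n_taxa = 10, n_samples_a = 12,
                                  n_samples_b = 12,
                                  blocks = list(c(4, 0.6)),
                                  planted_subset = integer(0), seed = 5)))
  a <- cohort_subset(gen$study, "A")
  perm <- withr::with_seed(9, sample(a$samples))
  a_perm <- a
  a_perm$samples <- perm
  a_perm$abundance <- a$abundance[, perm]
  a_perm$cohort <- a$cohort[perm]
  for (est in c("spearman", "pearson", "sparcc")) {
    cfg <- network_config(estimator = est)
    expect_equal(estimate_correlations(a, cfg),
                 estimate_correlations(a_perm, cfg),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("pearson estimates recover generating log-normal correlations", {
  # 5 focal taxa behind a dominant near-constant reference taxon, so the
  # closure divisor is essentially constant and the generator's correlation
  # matrix is a valid oracle for the focal block
  spec <- synthetic_spec(n_taxa = 6, n_samples_a = 300, n_samples_b = 4,
                         blocks = list(c(1, 0), c(3, 0.6)),
                         planted_subset = integer(0),
                         mean_logabund = c(5, rep(0, 5)),
                         sd_logabund = c(0.01, rep(0.2, 5)),
                         zero_inflation = 0, seed = 21)
  gen <- generate_study(spec)
  a <- cohort_subset(gen$study, "A")
  corr <- estimate_correlations(a, network_config(estimator = "pearson"))
  focal <- 2:6
  expect_lt(max(abs(corr[focal, focal] - gen$truth$corr_a[focal, focal])),
            0.15)
})

test_that("network thresholding matches an exhaustive scan and keeps signs", {
  corr <- withr::with_seed(11, {
    m <- matrix(runif(36, -1, 1), 6, 6)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    m
  })
  cfg <- network_config(min_abs_corr = 0.4)
  net <- build_network(corr, cfg)
  for (i in 1:6) {
    for (j in 1:6) {
      if (i == j) {
        expect_equal(net$A[i, j], 0)
        expect_equal(net$W[i, j], 1)
      } else if (abs(corr[i, j]) >= 0.4) {
        expect_equal(net$A[i, j], 1)
        expect_equal(net$W[i, j], abs(corr[i, j]))
        expect_equal(net$sign[i, j], sign(corr[i, j]))
      } else {
        expect_equal(net$A[i, j], 0)
        expect_equal(net$W[i, j], 0)
        expect_equal(net$sign[i, j], 0)
      }
    }
  }

  # negative edge above threshold: retained with magnitude weight
  c2 <- diag(2); c2[1, 2] <- c2[2, 1] <- -0.6
  n2 <- build_network(c2, network_config(min_abs_corr = 0.5))
  expect_equal(n2$A[1, 2], 1)
  expect_equal(n2$sign[1, 2], -1)
  expect_equal(n2$W[1, 2], 0.6)
  # below threshold: no edge
  c3 <- diag(2); c3[1, 2] <- c3[2, 1] <- 0.3
  expect_equal(build_network(c3, network_config(min_abs_corr = 0.5))$A[1, 2], 0)

  # threshold 0 on a dense matrix gives the complete graph minus loops
  dense <- build_network(corr, network_config(min_abs_corr = 0))
  offdiag <- dense$A[upper.tri(dense$A)]
  expect_true(all(offdiag == (corr[upper.tri(corr)] != 0) * 1))
  expect_equal(sum(diag(dense$A)), 0)
})

test_that("P/N ratio counts signs like a brute-force tally", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.5
  W[1, 3] <- W[3, 1] <- 0.6
  W[2, 3] <- W[3, 2] <- 0.7
  W[3, 4] <- W[4, 3] <- 0.4
  sgn <- sign(W)
  sgn[3, 4] <- sgn[4, 3] <- -1
  diag(W) <- 1
  net <- sna_network_from_w(W, sign = sgn, A = (sgn != 0) * 1)
  r <- pn_ratio(net)
  expect_equal(as.numeric(r), 3)

  for (seed in 1:10) {
    rn <- random_signed_network(8, p_edge = 0.6, seed = seed)
    counted <- oracle_pn(rn)
    r2 <- pn_ratio(rn)
    if (counted["neg"] == 0 && counted["pos"] > 0) {
      expect_true(is.infinite(r2))
    } else if (sum(counted) == 0) {
      expect_true(is.nan(as.numeric(r2)))
    } else {
      expect_equal(as.numeric(r2),
                   unname(counted["pos"] / counted["neg"]))
    }
    # ratio of the sign-flipped copy is the reciprocal
    flip <- rn
    flip$sign <- -rn$sign
    r3 <- pn_ratio(flip)
    if (is.finite(r2) && is.finite(r3) && as.numeric(r2) > 0) {
      expect_equal(as.numeric(r2) * as.numeric(r3), 1)
    }
  }
})

test_that("positive-only P/N formats as the dash convention", {
  W <- matrix(0.5, 3, 3); diag(W) <- 1
  net <- sna_network_from_w(W)
  r <- pn_ratio(net)
  expect_true(is.infinite(as.numeric(r)))
  expect_equal(format_pn(r), "-")
  expect_equal(format_pn(pn_ratio(sna_network_from_w(diag(3)))), "NA")
  expect_equal(format_pn(3), "3")
})

test_that("edge subsets restrict the P/N count and reject non-edges", {
  net <- random_signed_network(6, p_edge = 1, seed = 2)
  sub <- tidy(net)[1:3, c("taxon_i", "taxon_j")]
  r <- pn_ratio(net, edge_subset = sub)
  signs <- tidy(net)$sign[1:3]
  expect_equal(attr(r, "n_pos"), sum(signs > 0))
  expect_equal(attr(r, "n_neg"), sum(signs < 0))
  none <- sna_network_from_w(diag(6))
  expect_error(pn_ratio(none, edge_subset = sub), "non-edges")
})

test_that("sparcc recovers strong compositional associations", {
  spec <- synthetic_spec(n_taxa = 12, n_samples_a = 150, n_samples_b = 4,
                         blocks = list(c(4, 0.8)),
                         planted_subset = integer(0),
                         mean_logabund = rep(0, 12), sd_logabund = 1,
                         zero_inflation = 0, seed = 33)
  gen <- generate_study(spec)
  a <- cohort_subset(gen$study, "A")
  corr <- estimate_correlations(a, network_config(estimator = "sparcc"))
  in_block <- corr[1:4, 1:4][upper.tri(matrix(0, 4, 4))]
  out_block <- corr[5:12, 5:12][upper.tri(matrix(0, 8, 8))]
  expect_gt(min(in_block), 0.4)           # correlated block found
  expect_lt(max(abs(out_block)), 0.35)    # background stays near zero
  expect_equal(unname(diag(corr)), rep(1, 12))
  expect_equal(corr, t(corr), ignore_attr = TRUE)
})
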