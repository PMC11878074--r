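test_that("force is the stiffness matrix applied to the displacement", {
  W <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  net <- sna_network_from_w(W)
  expect_equal(compute_force(net, c(1, 1)), c(1.5, 1.5), ignore_attr = TRUE)
  expect_equal(compute_force(net, c(0, 0)), c(0, 0), ignore_attr = TRUE)
  # linearity: scaling d scales f
  d <- c(0.3, -0.7)
  expect_equal(compute_force(net, 5 * d), 5 * compute_force(net, d))
  expect_error(compute_force(net, c(1, 2, 3)), "length")
})

test_that("degree vector applied as force to an unweighted network causes unit displacements", {
  # chain of 3 nodes: degrees (1, 2, 1)
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.9
  W[2, 3] <- W[3, 2] <- 0.4
  diag(W) <- 1
  net <- sna_network_from_w(W)
  expect_equal(compute_force(net, rep(1, 3), unweighted = TRUE),
               c(1, 2, 1), ignore_attr = TRUE)

  # triangle: invertible adjacency, so the solve recovers the unit vector
  tri <- sna_network_from_w(matrix(1, 3, 3))
  deg <- compute_force(tri, rep(1, 3), unweighted = TRUE)
  d <- compute_displacement(tri, deg, unweighted = TRUE)
  expect_equal(as.numeric(d), rep(1, 3), tolerance = 1e-10)
})

test_that("displacement solves the stiffness system", {
  ident <- sna_network_from_w(diag(2))
  expect_equal(as.numeric(compute_displacement(ident, c(3, 7))), c(3, 7))

  diag_net <- sna_network_from_w(diag(c(2, 4)))
  expect_equal(as.numeric(compute_displacement(diag_net, c(2, 4))), c(1, 1))

  # round trip on a random well-conditioned system
  for (seed in 1:5) {
    net <- random_signed_network(8, p_edge = 0.4, seed = seed)
    d0 <- withr::with_seed(seed + 100, rnorm(8))
    f <- compute_force(net, d0)
    d <- compute_displacement(net, f)
    expect_false(attr(d, "regularized"))
    expect_lt(max(abs(as.numeric(d) - d0)), 1e-8)
  }
})

test_that("singular stiffness matrices fall back to a flagged minimum-norm solve", {
  # two identical rows make W singular
  W <- matrix(c(1, 1, 1, 1), 2, 2)
  net <- sna_network_from_w(W)
  d <- compute_displacement(net, c(2, 2))
  expect_true(attr(d, "regularized"))
  # minimum-norm solution of x1 + x2 = 2 is (1, 1)
  expect_equal(as.numeric(d), c(1, 1), tolerance = 1e-8)
})

test_that("stiffness scale satisfies its defining identity diag(s) W y = x", {
  W <- matrix(c(1, 1, 1, 2), 2, 2)
  net <- sna_network_from_w(W)
  s <- compute_stiffness_scale(net, x = c(2, 3), y = c(1, 1))
  expect_equal(s, c(1, 1), ignore_attr = TRUE)
  K <- net$W * net$A; diag(K) <- diag(net$W)
  expect_equal(as.numeric(diag(s) %*% K %*% c(1, 1)), c(2, 3))

  expect_equal(compute_stiffness_scale(net, x = c(0, 0), y = c(1, 1)),
               c(0, 0), ignore_attr = TRUE)

  for (seed in 1:5) {
    net6 <- random_signed_network(6, p_edge = 0.7, seed = seed)
    at <- random_attributes(6, seed = seed)
    s6 <- compute_stiffness_scale(net6, x = at$x_b, y = at$x_a)
    K6 <- net6$W * net6$A; diag(K6) <- diag(net6$W)
    ok <- !is.na(s6)
    expect_lt(max(abs((s6 * drop(K6 %*% at$x_a))[ok] - at$x_b[ok])), 1e-10)
  }

  # numerically-zero denominators are flagged NA, not returned as 0
  zero_y <- compute_stiffness_scale(sna_network_from_w(diag(c(0, 1))),
                                    x = c(1, 1), y = c(1, 1))
  expect_true(is.na(zero_y[1]))
  expect_equal(unname(zero_y[2]), 1)
})

test_that("perturbation matrix is the elementwise relative-change ratio", {
  P <- compute_perturbation_matrix(c(1, 2), c(2, 4))
  expect_equal(P$G, matrix(1, 2, 2))  # proportional change everywhere

  # r_j = 0 masks column j
  P2 <- compute_perturbation_matrix(c(1, 2), c(2, 2))
  expect_true(all(is.na(P2$G[, 2])))
  expect_false(anyNA(P2$G[, 1]))

  for (seed in 1:5) {
    at <- random_attributes(5, seed = seed)
    P3 <- compute_perturbation_matrix(at$x_a, at$x_b)
    r <- (at$x_b - at$x_a) / pmax(at$x_a, 1e-6)
    for (i in 1:5) {
      for (j in 1:5) {
        if (abs(r[j]) > 1e-12) {
          expect_equal(P3$G[i, j], abs(r[i] / r[j]))
        } else {
          expect_true(is.na(P3$G[i, j]))
        }
      }
    }
    # reciprocal symmetry on mutually defined entries
    def <- P3$defined & t(P3$defined) & !is.na(P3$G) & P3$G > 0
    expect_equal(P3$G[def] * t(P3$G)[def], rep(1, sum(def)))
  }
})

test_that("impact and stability match brute-force loops and degree limits", {
  # two mutually connected nodes with unit perturbations
  net2 <- sna_network_from_w(matrix(c(1, 1, 1, 1), 2, 2))
  P1 <- compute_perturbation_matrix(c(1, 2), c(2, 4))
  expect_equal(compute_impact(net2, P1), c(1, 1))
  expect_equal(compute_stability(net2, P1), c(1, 1))

  # star with 4 leaves, G all ones: center stability = 1/degree = 0.25
  Ws <- matrix(0, 5, 5)
  Ws[1, 2:5] <- Ws[2:5, 1] <- 0.5
  diag(Ws) <- 1
  star <- sna_network_from_w(Ws)
  Pones <- compute_perturbation_matrix(rep(1, 5), rep(2, 5))
  expect_equal(compute_stability(star, Pones)[1], 0.25)
  expect_equal(compute_impact(star, Pones)[1], 4)  # = degree when G is 1
  # isolated node: undefined, not zero
  Wi <- diag(3)
  Wi[1, 2] <- Wi[2, 1] <- 0.5
  iso <- sna_network_from_w(Wi)
  Pi <- compute_perturbation_matrix(c(1, 1, 1), c(2, 3, 4))
  expect_true(is.na(compute_impact(iso, Pi)[3]))
  expect_true(is.na(compute_stability(iso, Pi)[3]))

  # single neighbour with G_ij = 2 gives S = 1/2
  Wp <- diag(2); Wp[1, 2] <- Wp[2, 1] <- 0.5
  pair <- sna_network_from_w(Wp)
  Pg <- compute_perturbation_matrix(c(1, 1), c(3, 2))  # r = (2, 1)
  expect_equal(compute_stability(pair, Pg)[1], 0.5)

  for (seed in 1:10) {
    net <- random_signed_network(6, p_edge = 0.5, seed = seed)
    at <- random_attributes(6, seed = seed + 50)
    P <- compute_perturbation_matrix(at$x_a, at$x_b)
    expect_equal(compute_impact(net, P), oracle_impact(net$A, P$G))
    expect_equal(compute_stability(net, P), oracle_stability(net$A, P$G))
  }
})

test_that("profile assembles exactly the standalone operations", {
  net <- random_signed_network(10, p_edge = 0.4, seed = 8)
  at <- random_attributes(10, seed = 8)
  prof <- suppressMessages(
    compute_profile(net, x_a = at$x_a, x_b = at$x_b))

  d_obs <- at$x_b - at$x_a
  f <- compute_force(net, d_obs)
  expect_equal(prof$force, unname(f))
  expect_equal(prof$displacement,
               unname(as.numeric(compute_displacement(net, f))))
  expect_equal(prof$stiffness_scale,
               unname(compute_stiffness_scale(net, x = at$x_b, y = at$x_a)))
  P <- compute_perturbation_matrix(at$x_a, at$x_b)
  expect_equal(prof$impact, unname(compute_impact(net, P)))
  expect_equal(prof$stability, unname(suppressMessages(compute_stability(net, P))))
})

test_that("no displacement means zero force and undefined perturbations", {
  net <- sna_network_from_w(diag(4))
  x <- c(0.1, 0.2, 0.3, 0.4)
  prof <- compute_profile(net, x_a = x, x_b = x)
  expect_equal(prof$force, rep(0, 4))
  expect_equal(prof$displacement, rep(0, 4))
  expect_true(all(is.na(prof$impact)))
  expect_true(all(is.na(prof$stability)))
})

test_that("stiffness parameters are invariant under taxon relabeling", {
  net <- random_signed_network(7, p_edge = 0.5, seed = 13)
  at <- random_attributes(7, seed = 13)
  prof <- suppressMessages(compute_profile(net, at$x_a, at$x_b))

  perm <- withr::with_seed(14, sample(7))
  net_p <- sna_network_from_w(net$W[perm, perm],
                              sign = net$sign[perm, perm],
                              A = net$A[perm, perm])
  prof_p <- suppressMessages(
    compute_profile(net_p, at$x_a[perm], at$x_b[perm]))
  for (col in c("force", "displacement", "stiffness_scale",
                "impact", "stability")) {
    expect_equal(prof_p[[col]], prof[[col]][perm], tolerance = 1e-10)
  }
})

test_that("profile tidiers reshape and summarise", {
  net <- random_signed_network(5, p_edge = 0.6, seed = 4)
  at <- random_attributes(5, seed = 4)
  prof <- suppressMessages(compute_profile(net, at$x_a, at$x_b))
  long <- tidy(prof)
  expect_equal(nrow(long), 5 * 5)
  gl <- glance(prof)
  expect_setequal(gl$parameter,
                  c("force", "displacement", "stiffness_scale",
                    "impact", "stability"))
  frow <- gl[gl$parameter == "force", ]
  expect_equal(frow$mean, mean(prof$force))
  expect_equal(frow$min, min(prof$force))
  expect_equal(frow$max, max(prof$force))
})
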