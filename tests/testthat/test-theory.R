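test_that("connectivity mu is the normalized G-ball volume", {
  expect_equal(connectivity_mu(6, 6), 1)
  expect_equal(connectivity_mu(6, 2), 1 / 3) # (6 + 15) / 63
  expect_error(connectivity_mu(6, 0), "\\[1, B\\]")
  expect_error(connectivity_mu(6, 7), "\\[1, B\\]")
  # against exhaustive enumeration at B = 8
  for (G in c(1, 3, 8)) {
    expect_equal(connectivity_mu(8, G),
                 nrow(bitstrings_within(rep(0L, 8), G)) / (2^8 - 1))
  }
  # monotone nondecreasing in G; log-space branch consistent with direct sums
  mus <- vapply(1:20, function(G) connectivity_mu(20, G), numeric(1))
  expect_true(all(diff(mus) > 0))
  expect_equal(exp(hammingnet:::.logsumexp(lchoose(20, 1:5)) - 20 * log(2)) / (1 - 2^-20),
               connectivity_mu(20, 5), tolerance = 1e-12)
})

test_that("degree distribution is binomial with mean mu (N - 1)", {
  expect_equal(degree_pmf(10, 0), c(1, rep(0, 9)))
  expect_equal(degree_pmf(10, 1), c(rep(0, 9), 1))
  for (mu in c(0.001, 0.3, 0.9)) {
    g <- degree_pmf(512, mu)
    expect_equal(sum(g), 1, tolerance = 1e-12)
    expect_equal(sum((0:511) * g), mu * 511, tolerance = 1e-9)
  }
})

test_that("critical connectivity and the giant-component fixed point behave across regimes", {
  expect_equal(mu_critical(3), 1)
  expect_equal(mu_critical(1024), 1 / 1022)
  expect_error(mu_critical(2), "N >= 3")
  # subcritical and critical: no giant component
  expect_equal(solve_giant(0.5 / 1022, 1024), list(u = 1, S = 0))
  expect_equal(solve_giant(mu_critical(1024), 1024), list(u = 1, S = 0))
  # complete graph
  fp <- solve_giant(1, 1024)
  expect_equal(fp$u, 0)
  expect_equal(fp$S, 1)
  # supercritical root solves the fixed-point equation
  mu <- 3 / 1022
  fp <- solve_giant(mu, 1024)
  expect_lt(fp$u, 1)
  expect_equal(fp$u, (1 - mu + mu * fp$u)^1022, tolerance = 1e-9)
})

test_that("large-N limit matches an independent bisection and the finite-N solver", {
  expect_equal(solve_giant_largeN(1)$S, 0)
  expect_equal(solve_giant_largeN(0.3)$S, 0)
  expect_gt(solve_giant_largeN(50)$S, 0.999)
  # frozen value from the bisection oracle at ratio 2
  oracle <- bisect_giant_largeN(2)
  expect_equal(oracle$S, 0.796812, tolerance = 1e-5)
  expect_equal(solve_giant_largeN(2)$S, oracle$S, tolerance = 1e-8)
  # finite-N solver converges to the large-N limit
  N <- 1e4
  for (ratio in c(0.5, 1.5, 2, 3)) {
    fpN <- solve_giant(ratio * mu_critical(N), N)
    expect_equal(fpN$S, solve_giant_largeN(ratio)$S, tolerance = 1e-3)
  }
})

test_that("richness approximation interpolates its two limits and linearizes", {
  expect_equal(richness_approx(0), 1)
  expect_equal(richness_approx(1e6), 0.5)
  expect_lt(abs(richness_approx(0.2) - (1 - 0.1)), 0.01)
})

test_that("neighbour-pair probability matches enumeration and is symmetric", {
  # two distinct neighbours at distance 1 are at mutual distance 2
  for (B in c(4, 10, 20)) expect_equal(neighbor_pair_prob(B, 1, 1, 2), 1)
  # G = B: everything is within range
  expect_equal(neighbor_pair_prob(8, 3, 5, 8), 1)
  # exhaustive oracle at B = 6, H1 = H2 = 2, G = 2: all ordered pairs of
  # strings with two ones, counting pairs at mutual distance <= 2
  A <- all_bitstrings(6)
  S2 <- A[rowSums(A) == 2, ]
  D <- hamming_matrix(S2)
  n_all <- sum(D <= 2)                      # includes the 15 identical pairs
  n_distinct <- sum(D <= 2 & D > 0)
  expect_equal(neighbor_pair_prob(6, 2, 2, 2, identical = TRUE), n_all / 15^2)
  expect_equal(neighbor_pair_prob(6, 2, 2, 2), n_distinct / (15^2 - 15))
  # symmetry in (H1, H2) for all grids up to B = 12
  for (B in c(5, 9, 12)) {
    for (G in unique(c(1, 2, B %/% 2, B))) {
      for (H1 in 1:G) {
        for (H2 in 1:G) {
          expect_equal(neighbor_pair_prob(B, H1, H2, G),
                       neighbor_pair_prob(B, H2, H1, G), tolerance = 1e-12)
          expect_equal(neighbor_pair_prob(B, H1, H2, G, identical = TRUE),
                       neighbor_pair_prob(B, H2, H1, G, identical = TRUE),
                       tolerance = 1e-12)
        }
      }
    }
  }
  expect_error(neighbor_pair_prob(6, 3, 1, 2), "\\[1, G\\]")
})

test_that("analytic clustering matches its triple-sum form, the exhaustive network, and known limits", {
  # complete graph at G = B
  expect_equal(clustering_coeff(6, 6), 1)
  expect_equal(clustering_coeff(20, 20), 1)
  # triple-sum evaluation of the same quantity (as-printed convention),
  # B!/(h! (H1-h)! (H2-h)! (B-H1-H2+h)!) normalized by M_G^2
  triple_sum <- function(B, G) {
    MG <- sum(choose(B, 1:G))
    total <- 0
    for (H1 in 1:G) {
      for (H2 in 1:G) {
        h0 <- max(0, floor((H1 + H2 - G + 1) / 2))
        for (h in h0:min(H1, H2)) {
          if (B - H1 - H2 + h < 0) next
          total <- total + exp(lfactorial(B) - lfactorial(h) - lfactorial(H1 - h) -
                                 lfactorial(H2 - h) - lfactorial(B - H1 - H2 + h))
        }
      }
    }
    total / MG^2
  }
  for (cfg in list(c(6, 2), c(10, 3), c(12, 6))) {
    expect_equal(clustering_coeff(cfg[1], cfg[2], identical = TRUE),
                 triple_sum(cfg[1], cfg[2]), tolerance = 1e-10)
  }
  # exhaustive oracle: mean local clustering of the full 2^7-node network
  A <- all_bitstrings(7)
  for (G in 1:3) {
    g <- similarity_network(A, G)
    expect_lt(abs(clustering_coeff(7, G) - mean_clustering(g)), 0.02)
  }
  # rises toward 1 with G (small-G parity oscillations aside: pairs at
  # distances (H, H) are automatically linked once 2H <= G, so C dips when a
  # new odd shell opens), and sits far above the Erdos-Renyi level when sparse
  cs <- vapply(1:20, function(G) clustering_coeff(20, G), numeric(1))
  expect_true(all(diff(cs[5:20]) > -1e-12))
  expect_gt(cs[10], cs[2])
  z <- connectivity_mu(20, 3) * 1023
  expect_gt(clustering_coeff(20, 3) / (z / 1023), 50)
})

test_that("theory summary collects consistent derived scalars", {
  ts <- theory_summary(1024, 20, 3)
  expect_s3_class(ts, "theory_summary")
  expect_equal(ts$mu, ts$M_G / (2^20 - 1))
  expect_equal(ts$z, ts$mu * 1023)
  expect_equal(ts$ratio, ts$mu / ts$mu_c)
  expect_equal(ts$S, solve_giant(ts$mu, 1024)$S)
  expect_output(print(ts), "mu/mu_c")
})
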