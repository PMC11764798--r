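# Closed-form results for bit-string similarity networks: connectivity
# parameter mu, binomial degree distribution, giant-component fixed point,
# richness approximation, and the combinatorial mean clustering coefficient.

#' Connectivity parameter mu of a similarity network
#'
#' The probability that a uniformly chosen string different from b lies
#' within Hamming distance G of b:
#' `mu = M_G / (M - 1)` with `M = 2^B` and
#' `M_G = sum_{H=1}^{G} choose(B, H)`. mu takes discrete increasing values
#' as G runs from 1 to B, reaching 1 at G = B.
#'
#' @param B String length.
#' @param G Hamming threshold, `1 <= G <= B`.
#' @return mu in (0, 1]. Computed from exact binomial-coefficient sums for
#'   B <= 1000 and in log space beyond.
#' @examples
#' connectivity_mu(6, 2) # 21/63 = 1/3
#' @export
connectivity_mu <- function(B, G) {
  stopifnot(B >= 1)
  if (G < 1 || G > B) stop("G must lie in [1, B]")
  if (B <= 1000) {
    sum(choose(B, seq_len(G))) / (2^B - 1)
  } else {
    exp(.logsumexp(lchoose(B, seq_len(G))) - B * log(2))
  }
}

#' Critical connectivity for the giant component
#'
#' A giant component appears when mu exceeds `mu_c = 1/(N - 2)`; for large N
#' the ratio mu/mu_c approximates the mean degree z.
#'
#' @param N Network size (at least 3).
#' @export
mu_critical <- function(N) {
  if (N <= 2) stop("mu_c is defined for N >= 3")
  1 / (N - 2)
}

#' Degree distribution of a similarity network
#'
#' Each of the other N-1 nodes is independently within reach with
#' probability mu, so the degree is binomial:
#' `g_k = choose(N-1, k) mu^k (1-mu)^(N-1-k)`, with mean z = mu (N-1) -
#' identical to an Erdos-Renyi graph with `mu N(N-1)/2` links.
#'
#' @param N Network size.
#' @param mu Connectivity parameter in `[0, 1]`.
#' @return Numeric vector of probabilities for k = 0..N-1.
#' @export
degree_pmf <- function(N, mu) {
  stopifnot(N >= 2, mu >= 0, mu <= 1)
  dbinom(0:(N - 1), N - 1, mu)
}

#' Giant-component fixed point at finite N
#'
#' Solves `u = (1 - mu + mu u)^(N-2)` for the smallest root u in `[0, 1]`
#' (the extinction probability of the branching process generated by the
#' degree distribution) by bracketed root finding, and returns the giant
#' fraction `S = 1 - u^((N-1)/(N-2))`. Below the critical point
#' (`mu <= 1/(N-2)`) the only root is u = 1 and S = 0.
#'
#' @param mu Connectivity parameter in `[0, 1]`.
#' @param N Network size (at least 3).
#' @param tol Root tolerance (default 1e-12).
#' @return List with elements `u` and `S`.
#' @export
solve_giant <- function(mu, N, tol = 1e-12) {
  stopifnot(mu >= 0, mu <= 1, N >= 3)
  if (mu <= 1 / (N - 2)) return(list(u = 1, S = 0))
  f <- function(u) u - (1 - mu + mu * u)^(N - 2)
  hi <- 1 - 1e-12
  if (f(hi) <= 0) return(list(u = 1, S = 0))  # numerically at criticality
  r <- uniroot(f, c(0, hi), tol = tol, maxiter = 1000L)
  u <- r$root
  if (abs(f(u)) > 1e-8) stop("giant-component fixed point did not converge")
  list(u = u, S = 1 - u^((N - 1) / (N - 2)))
}

#' Giant-component fixed point in the large-N limit
#'
#' For N >> 1 the fixed point depends on (N, B, G) only through the ratio
#' r = mu/mu_c: `u = exp(-r (1 - u))`, `S = 1 - u`. S = 0 for r <= 1.
#'
#' @param ratio mu/mu_c (nonnegative).
#' @param tol Root tolerance (default 1e-12).
#' @return List with elements `u` and `S`.
#' @examples
#' solve_giant_largeN(2)$S # ~0.7968
#' @export
solve_giant_largeN <- function(ratio, tol = 1e-12) {
  stopifnot(ratio >= 0)
  if (ratio <= 1) return(list(u = 1, S = 0))
  f <- function(u) u - exp(-ratio * (1 - u))
  hi <- 1 - 1e-12
  if (f(hi) <= 0) return(list(u = 1, S = 0))
  r <- uniroot(f, c(0, hi), tol = tol, maxiter = 1000L)
  u <- r$root
  if (abs(f(u)) > 1e-8) stop("giant-component fixed point did not converge")
  list(u = u, S = 1 - u)
}

#' Small-component approximation to the richness
#'
#' The richness R is the number of connected components divided by N.
#' Counting isolated nodes (`exp(-r)` per node for large N) and assuming all
#' remaining nodes pair up into two-node components gives
#' `R = exp(-r) + (1 - exp(-r))/2`, which linearizes to `1 - r/2` for small
#' r = mu/mu_c and describes the measured richness up to r ~ 1.
#'
#' @param ratio mu/mu_c (nonnegative).
#' @export
richness_approx <- function(ratio) {
  stopifnot(ratio >= 0)
  exp(-ratio) + (1 - exp(-ratio)) / 2
}

#' Probability that two neighbours of a node are mutual neighbours
#'
#' For a reference string b0 and two strings at distances H1 and H2 from it,
#' the number h of positions where their differing bits coincide follows a
#' hypergeometric law, and their mutual distance is g = H1 + H2 - 2h. The
#' probability that g <= G is the hypergeometric tail over
#' `h >= h0 = max(0, floor((H1 + H2 - G + 1)/2))`. The expression is
#' symmetric in (H1, H2).
#'
#' The h = H1 = H2 outcome has g = 0, i.e. the two strings are identical -
#' impossible between distinct network nodes. By default that outcome is
#' removed from both the numerator and the normalization (`identical =
#' FALSE`), which is the version matching measured networks; `identical =
#' TRUE` keeps the full hypergeometric tail. In the degenerate case where
#' distinct pairs cannot exist at all (H1 = H2 = B), the unconditional value
#' is returned.
#'
#' @param B String length.
#' @param H1,H2 Distances from the reference string, in `[1, G]`.
#' @param G Hamming threshold, `1 <= G <= B`.
#' @param identical Include the identical-string outcome (default `FALSE`).
#' @return Probability in `[0, 1]`.
#' @export
neighbor_pair_prob <- function(B, H1, H2, G, identical = FALSE) {
  stopifnot(B >= 1)
  if (G < 1 || G > B) stop("G must lie in [1, B]")
  if (H1 < 1 || H1 > G || H2 < 1 || H2 > G) stop("H1 and H2 must lie in [1, G]")
  if (H1 > H2) { tmp <- H1; H1 <- H2; H2 <- tmp }
  h0 <- max(0, floor((H1 + H2 - G + 1) / 2))
  p <- phyper(h0 - 1, H1, B - H1, H2, lower.tail = FALSE)
  if (!identical && H1 == H2) {
    p0 <- dhyper(H1, H1, B - H1, H2)
    if (1 - p0 > 0) p <- (p - p0) / (1 - p0)
  }
  min(max(p, 0), 1)
}

#' Mean clustering coefficient of a similarity network
#'
#' The probability that two uniformly chosen neighbours of a node are
#' themselves neighbours, averaged over the distance profile of a
#' neighbourhood: distances H occur with weight `choose(B, H)/M_G`, so
#' `C = sum_{H1,H2=1}^{G} w(H1) w(H2) P(H1, H2)` with P from
#' [neighbor_pair_prob()]. Independent of the network size N; equals 1 at
#' G = B (complete graph) and greatly exceeds the Erdos-Renyi value z/(N-1)
#' at small G.
#'
#' @param B String length.
#' @param G Hamming threshold.
#' @param identical Convention for the identical-string outcome; see
#'   [neighbor_pair_prob()].
#' @return C in `[0, 1]`.
#' @export
clustering_coeff <- function(B, G, identical = FALSE) {
  stopifnot(B >= 1)
  if (G < 1 || G > B) stop("G must lie in [1, B]")
  lw <- lchoose(B, seq_len(G))
  w <- exp(lw - .logsumexp(lw))
  P <- matrix(0, G, G)
  for (i in seq_len(G)) {
    for (j in i:G) {
      P[i, j] <- P[j, i] <- neighbor_pair_prob(B, i, j, G, identical)
    }
  }
  drop(crossprod(w, P %*% w))
}

#' Analytic summary of a similarity-network ensemble
#'
#' Collects the derived scalars for a parameter triple (N, B, G): the
#' neighbourhood volume M_G, connectivity mu, critical value mu_c, their
#' ratio, mean degree z, extinction probability u, giant fraction S,
#' clustering C and the small-component richness approximation.
#'
#' @param N Network size.
#' @param B String length.
#' @param G Hamming threshold.
#' @return Object of class `"theory_summary"` (a named list).
#' @examples
#' theory_summary(N = 1024, B = 20, G = 3)
#' @export
theory_summary <- function(N, B, G) {
  stopifnot(N >= 3, B >= 1)
  if (G < 1 || G > B) stop("G must lie in [1, B]")
  if (B <= 30 && N > 2^B) stop("N cannot exceed 2^B for a distinct set")
  mu <- connectivity_mu(B, G)
  mu_c <- mu_critical(N)
  fp <- solve_giant(mu, N)
  structure(list(
    N = N, B = B, G = G,
    M_G = if (B <= 1000) sum(choose(B, seq_len(G))) else exp(.logsumexp(lchoose(B, seq_len(G)))),
    mu = mu, mu_c = mu_c, ratio = mu / mu_c, z = mu * (N - 1),
    u = fp$u, S = fp$S,
    C = clustering_coeff(B, G),
    R_approx = richness_approx(mu / mu_c)
  ), class = "theory_summary")
}

#' @export
print.theory_summary <- function(x, digits = 4, ...) {
  cat("Bit-string similarity network, N =", x$N, " B =", x$B, " G =", x$G, "\n")
  cat(sprintf("  neighbourhood volume M_G : %.6g\n", x$M_G))
  cat(sprintf("  connectivity mu          : %.6g  (mu_c = %.6g, mu/mu_c = %.4g)\n",
              x$mu, x$mu_c, x$ratio))
  cat(sprintf("  mean degree z            : %.4g\n", x$z))
  cat(sprintf("  giant component S        : %.4g  (u = %.4g)\n", x$S, x$u))
  cat(sprintf("  mean clustering C        : %.4g\n", x$C))
  cat(sprintf("  richness approximation R : %.4g\n", x$R_approx))
  invisible(x)
}
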