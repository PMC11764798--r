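# Seeded experiment drivers: realization-averaged curves of the model's
# structural quantities (divergence trajectories; giant component and
# richness vs mu/mu_c; clustering, assortativity and geodesic distance vs
# G/B) with analytic columns attached where theory exists. Each driver
# derives one sub-seed per (experiment, grid point, replicate), so runs are
# bit-reproducible and grid subsets match the corresponding full-run rows.

.derive_seed <- function(master, point, rep) {
  as.integer((as.double(master) * 1009733 + point * 7919 + rep * 104729) %% 2147483629) + 1L
}

.exp_id <- c(divergence = 2L, giant = 3L, clustering = 5L, assortativity = 6L, geodesic = 7L)

# One random realization's upper-triangle distances plus index bookkeeping,
# shared by all network sweeps (one distance matrix serves every G).
.realization_distances <- function(N, B) {
  X <- random_bitstring_set(N, B)
  D <- hamming_matrix(X)
  list(dU = D[upper.tri(D)], up = .upper_pairs(N))
}

#' Convergence of neutral evolution to a random bit-string set
#'
#' Runs the neutral-evolution model for every (N, B) combination and
#' averages the divergence trajectory D(T) over `reps` independent seeds.
#' Defaults regenerate the reference conditions: N = 1024 with string
#' lengths spanning 10..100, 50 realizations, trajectories of 10 rescaled
#' time units (T up to 10 N B steps) sampled every 0.1 units.
#'
#' @param N,B Vectors of population sizes / string lengths (crossed).
#' @param t_max Trajectory length in rescaled time T/(N B).
#' @param record_dt Recording cadence in rescaled time.
#' @param reps Realizations per combination.
#' @param variant,exclude_parent Step rule, see [evolve_step()].
#' @param seed Master seed.
#' @param verbose Log per-combination progress to stderr.
#' @return Data frame with columns `N`, `B`, `step`, `rescaled_time`,
#'   `D_mean`, `D_sd`.
#' @export
experiment_divergence <- function(N = 1024, B = c(10, 20, 30, 50, 100),
                                  t_max = 10, record_dt = 0.1, reps = 50,
                                  variant = "random-death", exclude_parent = FALSE,
                                  seed = 1, verbose = FALSE) {
  grid <- expand.grid(N = N, B = B)
  out <- vector("list", nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    n <- grid$N[gi]; b <- grid$B[gi]
    total <- max(1L, round(t_max * n * b))
    every <- max(1L, round(record_dt * n * b))
    if (verbose) message("divergence: N=", n, " B=", b, " (", reps, " reps)")
    Dm <- NULL
    for (r in seq_len(reps)) {
      traj <- run_evolution(n, b, total, every, variant = variant,
                            exclude_parent = exclude_parent,
                            seed = .derive_seed(seed, .exp_id[["divergence"]] * 1000L + gi, r))
      if (is.null(Dm)) Dm <- matrix(NA_real_, reps, nrow(traj))
      Dm[r, ] <- traj$D
    }
    out[[gi]] <- data.frame(N = n, B = b, step = traj$step,
                            rescaled_time = traj$rescaled_time,
                            D_mean = colMeans(Dm), D_sd = apply(Dm, 2, sd))
  }
  do.call(rbind, out)
}

#' Giant component and richness across the connectivity transition
#'
#' For each threshold G, generates `reps` similarity networks on uniform
#' random distinct bit-string sets and records the mean and standard
#' deviation of the largest-component fraction S and the richness R,
#' together with the analytic columns: S from [solve_giant()] at the same
#' (mu, N) and the small-component approximation [richness_approx()].
#'
#' @param N Network size.
#' @param B String length.
#' @param G Integer vector of thresholds to sweep.
#' @param reps Realizations per G.
#' @param seed Master seed.
#' @param verbose Log progress to stderr.
#' @return Data frame with one row per G: `mu`, `ratio` (= mu/mu_c),
#'   `S_mean`, `S_sd`, `R_mean`, `R_sd`, `S_theory`, `R_theory`.
#' @export
experiment_giant_richness <- function(N = 1024, B = 20, G = 1:6, reps = 50,
                                      seed = 1, verbose = FALSE) {
  G <- sort(unique(as.integer(G)))
  S <- R <- matrix(NA_real_, reps, length(G))
  for (r in seq_len(reps)) {
    set.seed(.derive_seed(seed, .exp_id[["giant"]] * 1000L + B, r))
    rd <- .realization_distances(N, B)
    if (verbose) message("giant/richness: rep ", r, "/", reps)
    for (k in seq_along(G)) {
      sel <- which(rd$dU <= G[k])
      g <- .graph_from_pairs(rd$up$i[sel], rd$up$j[sel], N)
      comp <- igraph::components(g)
      S[r, k] <- max(comp$csize) / N
      R[r, k] <- comp$no / N
    }
  }
  mu <- vapply(G, function(g) connectivity_mu(B, g), numeric(1))
  ratio <- mu / mu_critical(N)
  data.frame(N = N, B = B, G = G, mu = mu, ratio = ratio,
             S_mean = colMeans(S), S_sd = apply(S, 2, sd),
             R_mean = colMeans(R), R_sd = apply(R, 2, sd),
             S_theory = vapply(mu, function(m) solve_giant(m, N)$S, numeric(1)),
             R_theory = richness_approx(ratio))
}

#' Empirical vs analytic mean clustering
#'
#' Measures the realization-averaged mean local clustering coefficient of
#' similarity networks for each G (nodes of degree < 2 excluded, see
#' [mean_clustering()]) next to the analytic [clustering_coeff()]. Local
#' coefficients are obtained from dense adjacency products, so a full
#' G-sweep at N ~ 1000 stays fast.
#'
#' @inheritParams experiment_giant_richness
#' @return Data frame with one row per G: `G_over_B`, `mu`, `ratio`,
#'   `C_mean`, `C_sd`, `n_defined` (realizations with at least one eligible
#'   node), `C_theory`.
#' @export
experiment_clustering <- function(N = 1024, B = 20, G = seq_len(B), reps = 50,
                                  seed = 1, verbose = FALSE) {
  G <- sort(unique(as.integer(G)))
  C <- matrix(NA_real_, reps, length(G))
  for (r in seq_len(reps)) {
    set.seed(.derive_seed(seed, .exp_id[["clustering"]] * 1000L + B, r))
    X <- random_bitstring_set(N, B)
    D <- hamming_matrix(X)
    if (verbose) message("clustering: rep ", r, "/", reps)
    for (k in seq_along(G)) {
      A <- (D <= G[k]) * 1
      diag(A) <- 0
      tri2 <- rowSums(tcrossprod(A) * A)     # = 2 * triangles through each node
      deg <- rowSums(A)
      eligible <- deg >= 2
      if (any(eligible))
        C[r, k] <- mean(tri2[eligible] / (deg[eligible] * (deg[eligible] - 1)))
    }
  }
  mu <- vapply(G, function(g) connectivity_mu(B, g), numeric(1))
  n_def <- colSums(!is.na(C))
  data.frame(N = N, B = B, G = G, G_over_B = G / B,
             mu = mu, ratio = mu / mu_critical(N),
             C_mean = colMeans(C, na.rm = TRUE), C_sd = apply(C, 2, sd, na.rm = TRUE),
             n_defined = n_def,
             C_theory = vapply(G, function(g) clustering_coeff(B, g), numeric(1)))
}

#' Degree assortativity across the threshold sweep
#'
#' Realization-averaged degree assortativity of similarity networks as a
#' function of G for one or more string lengths, with an optional matched
#' Erdos-Renyi comparator (same N, same number of links as each realization)
#' attached for one reference B. Assortativity is small but positive with a
#' peak at G/B < 0.5 and decays toward zero as connectivity grows; the
#' comparator stays at zero throughout.
#'
#' @param N Network size.
#' @param B Vector of string lengths.
#' @param G List of threshold vectors (one per B), or `NULL` for `1:B`.
#' @param reps Realizations per (B, G).
#' @param comparator_B String length whose sweep also gets ER comparator
#'   columns, or `NULL` for none.
#' @param seed Master seed.
#' @param verbose Log progress to stderr.
#' @return Data frame with one row per (B, G): `A_mean`, `A_sd`, `n_defined`
#'   and, where the comparator ran, `A_er_mean`, `A_er_sd`.
#' @export
experiment_assortativity <- function(N = 1024, B = c(20, 30, 50), G = NULL,
                                     reps = 50, comparator_B = 30, seed = 1,
                                     verbose = FALSE) {
  out <- vector("list", length(B))
  for (bi in seq_along(B)) {
    b <- B[bi]
    Gs <- if (is.null(G)) seq_len(b) else sort(unique(as.integer(G[[bi]])))
    withER <- !is.null(comparator_B) && b == comparator_B
    A <- Aer <- matrix(NA_real_, reps, length(Gs))
    for (r in seq_len(reps)) {
      set.seed(.derive_seed(seed, .exp_id[["assortativity"]] * 1000L + b, r))
      rd <- .realization_distances(N, b)
      if (verbose) message("assortativity: B=", b, " rep ", r, "/", reps)
      for (k in seq_along(Gs)) {
        sel <- which(rd$dU <= Gs[k])
        if (!length(sel)) next
        ii <- rd$up$i[sel]; jj <- rd$up$j[sel]
        deg <- tabulate(c(ii, jj), nbins = N)
        A[r, k] <- .assortativity_eq20(deg[ii], deg[jj])
        if (withER) {
          e <- .sample_edge_indices(N, length(sel))
          dg <- tabulate(c(e$i, e$j), nbins = N)
          Aer[r, k] <- .assortativity_eq20(dg[e$i], dg[e$j])
        }
      }
    }
    mu <- vapply(Gs, function(g) connectivity_mu(b, g), numeric(1))
    df <- data.frame(N = N, B = b, G = Gs, G_over_B = Gs / b,
                     mu = mu, ratio = mu / mu_critical(N),
                     A_mean = colMeans(A, na.rm = TRUE),
                     A_sd = apply(A, 2, sd, na.rm = TRUE),
                     n_defined = colSums(!is.na(A)),
                     A_er_mean = if (withER) colMeans(Aer, na.rm = TRUE) else NA_real_,
                     A_er_sd = if (withER) apply(Aer, 2, sd, na.rm = TRUE) else NA_real_)
    df$A_mean[is.nan(df$A_mean)] <- NA_real_
    df$A_er_mean[is.nan(df$A_er_mean)] <- NA_real_
    out[[bi]] <- df
  }
  do.call(rbind, out)
}

#' Mean geodesic distance across the threshold sweep
#'
#' Realization-averaged mean geodesic distance L of similarity networks
#' (finite-distance pairs only) with a matched Erdos-Renyi comparator of
#' equal size and link count. L ~ 1 both in the very sparse and in the
#' near-complete regime, with a sharp peak just above the giant-component
#' transition (mu/mu_c between 1 and 2).
#'
#' @param N Network size.
#' @param B String length.
#' @param G Thresholds to sweep; the default spans the transition zone and
#'   both sparse and dense tails for B = 100.
#' @param reps Realizations per G.
#' @param comparator Also measure the matched ER networks (default `TRUE`).
#' @param seed Master seed.
#' @param verbose Log progress to stderr.
#' @return Data frame with one row per G: `G_over_B`, `mu`, `ratio`,
#'   `L_mean`, `L_sd` and (with comparator) `L_er_mean`, `L_er_sd`.
#' @export
experiment_geodesic <- function(N = 1024, B = 100, G = c(29, 31:38, 45, 60),
                                reps = 20, comparator = TRUE, seed = 1,
                                verbose = FALSE) {
  G <- sort(unique(as.integer(G)))
  L <- Ler <- matrix(NA_real_, reps, length(G))
  for (r in seq_len(reps)) {
    set.seed(.derive_seed(seed, .exp_id[["geodesic"]] * 1000L + B, r))
    rd <- .realization_distances(N, B)
    if (verbose) message("geodesic: rep ", r, "/", reps)
    for (k in seq_along(G)) {
      sel <- which(rd$dU <= G[k])
      g <- .graph_from_pairs(rd$up$i[sel], rd$up$j[sel], N)
      L[r, k] <- mean_geodesic(g)
      if (comparator && length(sel)) {
        e <- .sample_edge_indices(N, length(sel))
        Ler[r, k] <- mean_geodesic(.graph_from_pairs(e$i, e$j, N))
      }
    }
  }
  mu <- vapply(G, function(g) connectivity_mu(B, g), numeric(1))
  data.frame(N = N, B = B, G = G, G_over_B = G / B,
             mu = mu, ratio = mu / mu_critical(N),
             L_mean = colMeans(L, na.rm = TRUE), L_sd = apply(L, 2, sd, na.rm = TRUE),
             L_er_mean = if (comparator) colMeans(Ler, na.rm = TRUE) else NA_real_,
             L_er_sd = if (comparator) apply(Ler, 2, sd, na.rm = TRUE) else NA_real_)
}
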