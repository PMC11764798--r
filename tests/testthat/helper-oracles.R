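# Independent oracle implementations used to validate the package's fast
# paths: integer XOR/popcount Hamming distance, brute-force pair loops,
# union-find components, Floyd-Warshall all-pairs shortest paths, and a
# large-N giant-component bisection.

# popcount of a nonnegative integer < 2^30
popcount <- function(x) {
  n <- 0L
  while (x > 0) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

bits_to_int <- function(b) sum(b * 2^(seq_along(b) - 1L))

# O(N^2 B) pairwise-distance histogram by explicit double loop
brute_hamming_freq <- function(X) {
  N <- nrow(X); B <- ncol(X)
  counts <- integer(B + 1L)
  for (i in seq_len(N - 1L)) {
    for (j in (i + 1L):N) {
      h <- sum(X[i, ] != X[j, ])
      counts[h + 1L] <- counts[h + 1L] + 1L
    }
  }
  counts / (N * (N - 1) / 2)
}

# edge list (i < j) by explicit double loop over a bit-string set
brute_edges <- function(X, G) {
  N <- nrow(X)
  out <- list()
  for (i in seq_len(N - 1L)) {
    for (j in (i + 1L):N) {
      if (sum(X[i, ] != X[j, ]) <= G) out[[length(out) + 1L]] <- c(i, j)
    }
  }
  if (length(out)) do.call(rbind, out) else matrix(integer(0), 0, 2)
}

# union-find connected components; returns membership vector
union_find_components <- function(N, edges) {
  parent <- seq_len(N)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(N), find, integer(1))
  match(roots, unique(roots))
}

# Floyd-Warshall mean finite geodesic distance over unordered pairs
floyd_warshall_mean <- function(N, edges) {
  d <- matrix(Inf, N, N)
  diag(d) <- 0
  for (k in seq_len(nrow(edges))) {
    d[edges[k, 1], edges[k, 2]] <- 1
    d[edges[k, 2], edges[k, 1]] <- 1
  }
  for (k in seq_len(N)) {
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  }
  v <- d[upper.tri(d)]
  v <- v[is.finite(v) & v > 0]
  if (!length(v)) NA_real_ else mean(v)
}

# smallest root of u = exp(-ratio (1 - u)) by plain bisection to 1e-10
bisect_giant_largeN <- function(ratio) {
  if (ratio <= 1) return(list(u = 1, S = 0))
  f <- function(u) u - exp(-ratio * (1 - u))
  lo <- 0; hi <- 1 - 1e-12
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-10) break
  }
  u <- (lo + hi) / 2
  list(u = u, S = 1 - u)
}

# random simple graph edge list for oracle comparisons
random_edges <- function(N, p) {
  e <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  e[runif(nrow(e)) < p, , drop = FALSE]
}

graph_from_edges <- function(N, edges) {
  g <- igraph::make_empty_graph(n = N, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  g
}
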