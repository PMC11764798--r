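# Similarity-network construction: link every pair of distinct bit strings
# whose Hamming distance is at most G. Graphs are igraph objects with graph
# attributes N, B, G and (where known) a vertex attribute "bitstring".

# Row/column indices of the upper triangle of an N x N matrix, in the same
# column-major order as x[upper.tri(x)].
.upper_pairs <- function(N) {
  list(i = sequence(seq_len(N - 1L)), j = rep(2:N, seq_len(N - 1L)))
}

# Map upper-triangle linear pair indices k (1..N(N-1)/2, column-major) to
# (i, j); inverse of k = (j-1)(j-2)/2 + i. The float guard corrects sqrt
# rounding at triangular-number boundaries.
.pair_index_to_ij <- function(k, N) {
  jp <- floor((sqrt(1 + 8 * k) - 1) / 2 + 1e-9)
  jp <- jp + (jp * (jp + 1) / 2 < k) - (jp * (jp - 1) / 2 >= k)
  list(i = as.integer(k - jp * (jp - 1) / 2), j = as.integer(jp + 1))
}

# Uniform sample of M distinct unordered pairs from N nodes (G(N, M) edges).
.sample_edge_indices <- function(N, M) {
  npairs <- N * (N - 1) / 2
  if (M < 0 || M > npairs) stop("edge count must lie in [0, N(N-1)/2]")
  .pair_index_to_ij(sample.int(npairs, M), N)
}

.graph_from_pairs <- function(i, j, N) {
  g <- igraph::make_empty_graph(n = N, directed = FALSE)
  if (length(i)) g <- igraph::add_edges(g, rbind(i, j))
  g
}

#' Build the similarity network of a distinct bit-string set
#'
#' Links exactly the pairs with `hamming_distance <= G`. Deterministic given
#' its inputs; the set must be distinct, since nodes are string identities.
#'
#' @param x 0/1 matrix with one bit string per row, rows distinct.
#' @param G Hamming threshold, `1 <= G <= B`.
#' @return An undirected simple `igraph` graph with graph attributes `N`,
#'   `B`, `G`, edge attribute `H` (the pair distance) and vertex attribute
#'   `bitstring`.
#' @examples
#' set.seed(1)
#' g <- similarity_network(random_bitstring_set(10, 6), G = 2)
#' @export
similarity_network <- function(x, G) {
  X <- .as_bit_matrix(x)
  B <- ncol(X)
  if (G < 1 || G > B) stop("G must lie in [1, B]")
  keys <- .bit_keys(X)
  if (anyDuplicated(keys)) stop("bit-string set contains duplicate strings")
  g <- network_from_distances(hamming_matrix(X), G)
  igraph::V(g)$bitstring <- keys
  g$B <- B
  g
}

#' Threshold a precomputed distance matrix into a network
#'
#' Sweeps over G reuse one distance matrix per realization; this applies the
#' threshold. `network_from_distances(hamming_matrix(X), G)` equals
#' `similarity_network(X, G)` up to vertex labels.
#'
#' @param D Symmetric integer distance matrix with zero diagonal.
#' @param G Threshold.
#' @return An undirected simple `igraph` graph with edge attribute `H`.
#' @export
network_from_distances <- function(D, G) {
  N <- nrow(D)
  up <- .upper_pairs(N)
  dU <- D[upper.tri(D)]
  sel <- which(dU <= G)
  g <- .graph_from_pairs(up$i[sel], up$j[sel], N)
  if (length(sel)) igraph::E(g)$H <- dU[sel]
  g$N <- N
  g$G <- G
  g
}

#' Erdos-Renyi comparator graph
#'
#' A uniform random simple graph with exactly `M` links (the G(N, M)
#' ensemble); the null model against which similarity networks are compared,
#' with `M = round(mu * N * (N - 1) / 2)` to match mean degree.
#'
#' @param N Number of nodes.
#' @param M Number of links, `0 <= M <= N(N-1)/2`.
#' @return An undirected simple `igraph` graph.
#' @export
er_graph <- function(N, M) {
  stopifnot(N >= 1)
  e <- .sample_edge_indices(N, M)
  g <- .graph_from_pairs(e$i, e$j, N)
  g$N <- N
  g
}

#' Write / read a network edge list
#'
#' Tab-separated file with a `# N=<N> B=<B> G=<G>` header line and columns
#' `i`, `j` (0-based node indices) and `H` (pair Hamming distance, `NA` if
#' unknown).
#'
#' @param g An `igraph` graph (as built by [similarity_network()]).
#' @param path File path.
#' @export
write_edge_list <- function(g, path) {
  n <- igraph::vcount(g)
  hdr <- sprintf("# N=%d B=%s G=%s", n,
                 if (is.null(g$B)) "NA" else g$B,
                 if (is.null(g$G)) "NA" else g$G)
  e <- igraph::ends(g, igraph::E(g), names = FALSE)
  H <- if ("H" %in% igraph::edge_attr_names(g)) igraph::E(g)$H else rep(NA, nrow(e))
  lines <- c(hdr, sprintf("%d\t%d\t%s", e[, 1] - 1L, e[, 2] - 1L, as.character(H)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_edge_list
#' @return `read_edge_list()`: the reconstructed `igraph` graph.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#"))
    stop("edge-list file must start with a '# N=... B=... G=...' header")
  get_field <- function(name) {
    m <- regmatches(lines[1], regexec(paste0(name, "=([0-9NA]+)"), lines[1]))[[1]][2]
    if (is.na(m) || m == "NA") NULL else as.integer(m)
  }
  N <- get_field("N")
  if (is.null(N)) stop("header must give N")
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body)) {
    parts <- do.call(rbind, strsplit(body, "\t"))
    i <- as.integer(parts[, 1]) + 1L
    j <- as.integer(parts[, 2]) + 1L
    g <- .graph_from_pairs(i, j, N)
    if (ncol(parts) >= 3) igraph::E(g)$H <- suppressWarnings(as.integer(parts[, 3]))
  } else {
    g <- .graph_from_pairs(integer(0), integer(0), N)
  }
  g$N <- N
  g$B <- get_field("B")
  g$G <- get_field("G")
  g
}
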