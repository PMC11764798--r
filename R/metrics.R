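# Empirical structural measurements on simple undirected graphs.

#' Connected components of a graph
#'
#' @param g An `igraph` graph.
#' @return List of integer vectors, one per component (maximal connected
#'   node sets), largest first.
#' @export
graph_components <- function(g) {
  comp <- igraph::components(g)
  parts <- split(seq_len(igraph::vcount(g)), comp$membership)
  parts[order(lengths(parts), decreasing = TRUE)]
}

#' Richness and largest-component fraction
#'
#' The richness R is the number of connected components divided by the
#' network size N - a diversity proxy in which each component is one
#' "species". R = 1 for an edgeless graph and approaches 1/N once the giant
#' component absorbs the network. The largest-component fraction is the
#' finite-network stand-in for the giant fraction S.
#'
#' @param g An `igraph` graph.
#' @export
richness <- function(g) {
  igraph::components(g)$no / igraph::vcount(g)
}

#' @rdname richness
#' @export
largest_component_fraction <- function(g) {
  max(igraph::components(g)$csize) / igraph::vcount(g)
}

#' Mean local clustering coefficient
#'
#' Average over nodes of the local coefficient C_i = (number of linked
#' neighbour pairs) / (number of neighbour pairs). C_i is undefined for
#' nodes of degree < 2; by default those are excluded from the average
#' (the analytic prediction is a probability over neighbour pairs, so
#' counting them as zero would bias sparse regimes), with
#' `low_degree = "zero"` available as the alternative convention.
#'
#' @param g An `igraph` graph.
#' @param low_degree `"exclude"` (default) or `"zero"`.
#' @return C in `[0, 1]`, or `NA` if no node has degree >= 2 under
#'   `"exclude"`.
#' @export
mean_clustering <- function(g, low_degree = c("exclude", "zero")) {
  low_degree <- match.arg(low_degree)
  ci <- igraph::transitivity(g, type = "local", isolates = "NaN")
  if (low_degree == "zero") ci[is.nan(ci)] <- 0
  if (all(is.nan(ci))) return(NA_real_)
  mean(ci, na.rm = TRUE)
}

# Pearson degree correlation over links from endpoint degree vectors:
# A = (4<k1 k2> - <k1+k2>^2) / (2<k1^2+k2^2> - <k1+k2>^2), averages over
# links; the symmetric form makes edge orientation irrelevant.
.assortativity_eq20 <- function(k1, k2) {
  s <- mean(k1 + k2)
  num <- 4 * mean(k1 * k2) - s^2
  den <- 2 * mean(k1^2 + k2^2) - s^2
  if (den <= .Machine$double.eps * max(1, s^2)) return(NA_real_)
  num / den
}

#' Degree assortativity over links
#'
#' Pearson correlation between the degrees at the two ends of each link,
#' computed in the orientation-free form
#' `A = (4<k1 k2> - <k1 + k2>^2) / (2<k1^2 + k2^2> - <k1 + k2>^2)`
#' with averages over all links. Positive when high-degree nodes attach to
#' each other, near zero for random link placement.
#'
#' @param g An `igraph` graph with at least one link.
#' @return A in `[-1, 1]`, or `NA` when the link-end degrees have zero
#'   variance (e.g. a regular or complete graph).
#' @examples
#' # a 3-node path is maximally disassortative
#' degree_assortativity(igraph::make_graph(c(1, 2, 2, 3), directed = FALSE))
#' @export
degree_assortativity <- function(g) {
  if (igraph::ecount(g) < 1) stop("assortativity needs at least one link")
  deg <- igraph::degree(g)
  e <- igraph::ends(g, igraph::E(g), names = FALSE)
  .assortativity_eq20(deg[e[, 1]], deg[e[, 2]])
}

#' Mean geodesic distance
#'
#' Arithmetic average of shortest-path lengths over all unordered pairs of
#' distinct nodes in the same connected component; pairs in different
#' components (infinite distance) are excluded. Equals 1 on a complete
#' graph, and again ~1 in very sparse graphs where components are single
#' links.
#'
#' @param g An `igraph` graph.
#' @return L >= 1, or `NA` when the graph has no link.
#' @export
mean_geodesic <- function(g) {
  if (igraph::ecount(g) < 1) return(NA_real_)
  igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
}

#' Full structural report of a network
#'
#' @param g An `igraph` graph.
#' @param low_degree Clustering convention, see [mean_clustering()].
#' @return Object of class `"network_report"`: list with the number of
#'   components, richness, largest-component fraction, mean clustering,
#'   degree assortativity (`NA` when undefined), mean geodesic distance and
#'   the degree histogram (counts for k = 0..max degree).
#' @export
network_report <- function(g, low_degree = c("exclude", "zero")) {
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  structure(list(
    n_nodes = igraph::vcount(g),
    n_links = igraph::ecount(g),
    n_components = comp$no,
    richness = comp$no / igraph::vcount(g),
    largest_component_fraction = max(comp$csize) / igraph::vcount(g),
    mean_clustering = mean_clustering(g, low_degree),
    assortativity = if (igraph::ecount(g) >= 1) degree_assortativity(g) else NA_real_,
    mean_geodesic = mean_geodesic(g),
    degree_histogram = tabulate(deg + 1L, nbins = max(deg) + 1L)
  ), class = "network_report")
}

#' @export
print.network_report <- function(x, ...) {
  cat("Network report:", x$n_nodes, "nodes,", x$n_links, "links\n")
  cat(sprintf("  components               : %d (richness R = %.4g)\n",
              x$n_components, x$richness))
  cat(sprintf("  largest component        : %.4g of the network\n",
              x$largest_component_fraction))
  cat(sprintf("  mean clustering C        : %s\n", format(x$mean_clustering, digits = 4)))
  cat(sprintf("  degree assortativity A   : %s\n", format(x$assortativity, digits = 4)))
  cat(sprintf("  mean geodesic distance L : %s\n", format(x$mean_geodesic, digits = 4)))
  invisible(x)
}
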