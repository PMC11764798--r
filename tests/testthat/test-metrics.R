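make_path3 <- function() graph_from_edges(3, rbind(c(1, 2), c(2, 3)))

test_that("components, richness and largest-component fraction cover the limiting graphs", {
  gK <- graph_from_edges(5, t(combn(5, 2)))
  expect_equal(length(graph_components(gK)), 1)
  expect_equal(richness(gK), 1 / 5)
  expect_equal(largest_component_fraction(gK), 1)
  g0 <- graph_from_edges(7, matrix(integer(0), 0, 2))
  expect_equal(length(graph_components(g0)), 7)
  expect_equal(richness(g0), 1)
  expect_equal(largest_component_fraction(g0), 1 / 7)
})

test_that("component partitions agree with an independent union-find", {
  set.seed(41)
  for (r in 1:20) {
    N <- sample(10:60, 1)
    edges <- random_edges(N, runif(1, 0.01, 0.1))
    g <- graph_from_edges(N, edges)
    mine <- igraph::components(g)$membership
    oracle <- union_find_components(N, edges)
    # same partition up to labelling
    expect_equal(length(unique(mine)), length(unique(oracle)))
    expect_true(all(tapply(oracle, mine, function(v) length(unique(v))) == 1))
  }
})

test_that("mean clustering handles hand-enumerated graphs under both conventions", {
  gK <- graph_from_edges(5, t(combn(5, 2)))
  expect_equal(mean_clustering(gK), 1)
  expect_equal(mean_clustering(make_path3()), 0) # middle node's neighbours unlinked
  # triangle plus pendant: the three degree->=2 nodes have C_i = (1, 1/3, 1)
  g <- graph_from_edges(4, rbind(c(1, 2), c(1, 3), c(2, 3), c(3, 4)))
  expect_equal(mean_clustering(g), (1 + 1 / 3 + 1) / 3)
  expect_equal(mean_clustering(g, low_degree = "zero"), (1 + 1 / 3 + 1 + 0) / 4)
  # no node of degree >= 2: undefined under the default convention
  g1 <- graph_from_edges(4, rbind(c(1, 2), c(3, 4)))
  expect_true(is.na(mean_clustering(g1)))
  expect_equal(mean_clustering(g1, low_degree = "zero"), 0)
})

test_that("degree assortativity reproduces hand calculations and the Pearson definition", {
  # path 0-1-2: links (1,2) and (2,1): A = (4*2 - 9)/(2*5 - 9) = -1
  expect_equal(degree_assortativity(make_path3()), -1)
  # complete graph: zero degree variance -> undefined
  expect_true(is.na(degree_assortativity(graph_from_edges(5, t(combn(5, 2))))))
  expect_error(degree_assortativity(graph_from_edges(3, matrix(integer(0), 0, 2))),
               "at least one link")
  # equals igraph's Pearson degree correlation on random graphs
  set.seed(42)
  for (r in 1:10) {
    g <- igraph::sample_gnp(60, 0.1)
    if (igraph::ecount(g) < 2) next
    a <- degree_assortativity(g)
    if (!is.na(a)) expect_equal(a, igraph::assortativity_degree(g), tolerance = 1e-12)
  }
})

test_that("large Erdos-Renyi graphs are unassorted", {
  set.seed(43)
  a <- replicate(50, degree_assortativity(er_graph(1024, 2048))) # z = 4
  expect_lt(abs(mean(a)), 0.02)
})

test_that("mean geodesic distance matches hand values and Floyd-Warshall", {
  expect_equal(mean_geodesic(graph_from_edges(5, t(combn(5, 2)))), 1)
  expect_equal(mean_geodesic(make_path3()), 4 / 3)
  expect_true(is.na(mean_geodesic(graph_from_edges(4, matrix(integer(0), 0, 2)))))
  set.seed(44)
  for (r in 1:10) {
    N <- sample(10:50, 1)
    edges <- random_edges(N, runif(1, 0.03, 0.2))
    if (!nrow(edges)) next
    g <- graph_from_edges(N, edges)
    expect_equal(mean_geodesic(g), floyd_warshall_mean(N, edges), tolerance = 1e-12)
  }
})

test_that("er_graph draws exactly M uniform links", {
  expect_equal(igraph::ecount(er_graph(10, 45)), 45) # complete
  expect_equal(igraph::ecount(er_graph(10, 0)), 0)
  set.seed(45)
  g <- er_graph(200, 400)
  expect_equal(igraph::ecount(g), 400)
  expect_false(igraph::any_multiple(g))
  expect_false(any(igraph::which_loop(g)))
  expect_equal(mean(igraph::degree(g)), 2 * 400 / 200)
  expect_error(er_graph(10, 46), "edge count")
})

test_that("network_report aggregates the individual metrics", {
  set.seed(46)
  g <- similarity_network(random_bitstring_set(60, 8), 2)
  rep <- network_report(g)
  expect_s3_class(rep, "network_report")
  expect_equal(rep$richness, richness(g))
  expect_equal(rep$mean_clustering, mean_clustering(g))
  expect_equal(rep$mean_geodesic, mean_geodesic(g))
  expect_equal(sum(rep$degree_histogram), 60)
  expect_output(print(rep), "richness")
})
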