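test_that("gini matches hand values and the pairwise-difference oracle", {
  expect_equal(gini(c(5, 5, 5, 5)), 0)
  expect_equal(gini(c(0, 1)), 0.5)          # pair sum 2 / (2 * 4 * 0.5)
  expect_equal(gini(rep(0, 10)), 0)         # all-zero convention
  set.seed(31)
  for (k in 1:20) {
    x <- stats::rexp(sample(2:200, 1))
    expect_equal(gini(x), brute_gini(x), tolerance = 1e-12)
  }
  expect_error(gini(c(1, -2)), "negative")
  expect_error(gini(numeric(0)), "empty")
})

test_that("gini is scale-invariant", {
  set.seed(32)
  for (k in 1:10) {
    x <- stats::rgamma(50, 0.7)
    const <- stats::runif(1, 0.01, 100)
    expect_equal(gini(const * x), gini(x), tolerance = 1e-12)
  }
})

test_that("giant component keeps the largest component, smallest-id on ties", {
  # connected network is returned whole
  ring <- ring_net(6)
  expect_equal(nrow(giant_component(ring)$placements), 6L)
  # 7-node component beats 3-node component
  e <- rbind(cbind(0:5, 1:6), c(7, 8), c(8, 9))
  gc <- giant_component(net_from_edges(10, e))
  expect_setequal(gc$placements$agent_id, 0:6)
  expect_equal(nrow(gc$edges), 6L)
  # two 5-node components: the one containing id 0 wins
  e2 <- rbind(cbind(0:3, 1:4), cbind(5:8, 6:9))
  gc2 <- giant_component(net_from_edges(10, e2))
  expect_setequal(gc2$placements$agent_id, 0:4)
})

test_that("degree statistics match closed forms", {
  expect_equal(degree_stats(ring_net(3)), c(degree_mean = 2, degree_gini = 0))
  st <- degree_stats(star_net(3))          # degrees 3,1,1,1
  expect_equal(st[["degree_mean"]], 1.5)
  expect_equal(st[["degree_gini"]], brute_gini(c(3, 1, 1, 1)))
  expect_equal(st[["degree_gini"]], 0.25)
})

test_that("edge-end assortativity is -1 on stars, undefined on regular graphs", {
  for (leaves in c(3, 5, 9)) {
    expect_equal(assortativity_edge(star_net(leaves)), -1, tolerance = 1e-12)
  }
  expect_true(is.na(assortativity_edge(ring_net(8))))
  expect_error(assortativity_edge(net_from_edges(2, cbind(0L, 1L))), "2 edges")
})

test_that("edge-end assortativity agrees with the reference implementation", {
  for (seed in 1:6) {
    net <- random_test_net(40, 0.12, seed)
    expect_equal(assortativity_edge(net),
                 igraph::assortativity_degree(as_igraph(net)),
                 tolerance = 1e-12)
  }
})

test_that("neighbour-mean assortativity matches hand computation and knn", {
  # path on 3 nodes: degrees (1,2,1), neighbour means (2,1,2)
  expect_equal(assortativity_neighbour_mean(path_net(3)), -1, tolerance = 1e-12)
  expect_true(is.na(assortativity_neighbour_mean(complete_net(5))))
  expect_error(assortativity_neighbour_mean(net_from_edges(3, cbind(0L, 1L))),
               "degree >= 1")
  for (seed in 1:4) {
    net <- random_test_net(30, 0.15, seed)
    g <- as_igraph(net)
    expect_equal(assortativity_neighbour_mean(net),
                 stats::cor(igraph::degree(g), igraph::knn(g)$knn),
                 tolerance = 1e-10)
  }
})

test_that("closeness is the reciprocal mean geodesic", {
  v <- closeness_values(path_net(3))
  expect_equal(v, c(2 / 3, 1, 2 / 3), tolerance = 1e-12)
  expect_error(closeness_values(net_from_edges(4, cbind(0L, 1L))), "giant_component")
  # cross-check against BFS distances on a random connected graph
  net <- random_test_net(25, 0.15, 9)
  d <- bfs_all_distances(adj_list(net))
  expect_equal(closeness_values(net), (25 - 1) / rowSums(d), tolerance = 1e-12)
})

test_that("betweenness matches hand values and the path-count oracle", {
  expect_equal(betweenness_values(path_net(3)), c(0, 1, 0))
  expect_equal(betweenness_values(complete_net(5)), rep(0, 5))
  expect_equal(betweenness_values(net_from_edges(2, cbind(0L, 1L))), c(0, 0))
  for (seed in 1:5) {
    n <- sample(10:30, 1)
    net <- random_test_net(n, 0.15, seed)
    expect_equal(betweenness_values(net), brute_betweenness(adj_list(net)),
                 tolerance = 1e-10)
  }
})

test_that("eigenvector centrality has unit norm and known star form", {
  v <- eigenvector_values(star_net(3))
  expect_equal(sum(v^2), 1, tolerance = 1e-10)
  expect_equal(sort(v, decreasing = TRUE),
               c(sqrt(1 / 2), rep(sqrt(1 / 6), 3)), tolerance = 1e-6)
  # regular connected graph: all entries equal, zero dispersion
  r <- eigenvector_values(ring_net(9))
  expect_equal(max(r) - min(r), 0, tolerance = 1e-8)
  expect_equal(gini(r), 0, tolerance = 1e-8)
})

test_that("local clustering and transitivity follow the triangle counts", {
  expect_equal(clustering_values(ring_net(3)), rep(1, 3))
  expect_equal(clustering_values(star_net(4)), rep(0, 5))
  leafy <- clustering_values(star_net(4), low_degree_as_zero = FALSE)
  expect_true(all(is.na(leafy[-1])) && leafy[1] == 0)
  expect_equal(global_transitivity(ring_net(3)), 1)
  expect_equal(global_transitivity(path_net(3)), 0)
  expect_true(is.na(global_transitivity(net_from_edges(2, cbind(0L, 1L)))))
})

test_that("geodesic statistics match closed forms and the BFS oracle", {
  expect_equal(geodesic_stats(complete_net(6)),
               c(geodesic_mean = 1, geodesic_gini = 0, diameter = 1))
  g3 <- geodesic_stats(path_net(3))        # pair distances {1, 1, 2}
  expect_equal(g3[["geodesic_mean"]], 4 / 3)
  expect_equal(g3[["diameter"]], 2)
  expect_error(geodesic_stats(net_from_edges(4, cbind(0L, 1L))), "giant_component")
  for (seed in 1:5) {
    net <- random_test_net(sample(10:30, 1), 0.2, seed)
    d <- bfs_all_distances(adj_list(net))
    pairs <- d[upper.tri(d)]
    got <- geodesic_stats(net)
    expect_equal(got[["geodesic_mean"]], mean(pairs))
    expect_equal(got[["diameter"]], max(pairs))
    expect_equal(got[["geodesic_gini"]], brute_gini(pairs), tolerance = 1e-12)
  }
})

test_that("the full summary is internally consistent with the standalone metrics", {
  cfg <- generator_config(150, torus_space(100, 100),
                          reach_discrete(c(12, 24), c(0.75, 0.25)), seed = 77)
  net <- generate_network(cfg)
  p <- network_properties(net)
  gc <- giant_component(net)
  expect_equal(p$n_giant, nrow(gc$placements))
  expect_equal(p$edges, nrow(gc$edges))
  expect_equal(p$density * p$n_giant * (p$n_giant - 1) / 2, p$edges)
  expect_equal(p$degree_mean, 2 * p$edges / p$n_giant)
  expect_equal(p$degree_gini, degree_stats(gc)[["degree_gini"]])
  expect_equal(p$assortativity_edge, assortativity_edge(gc))
  expect_equal(p$assortativity_neighbour_mean, assortativity_neighbour_mean(gc))
  expect_equal(p$closeness_mean, mean(closeness_values(gc)))
  expect_equal(p$betweenness_gini, gini(betweenness_values(gc)))
  expect_equal(p$eigenvector_gini, gini(eigenvector_values(gc)))
  expect_equal(p$clustering_mean, mean(clustering_values(gc)))
  expect_equal(p$transitivity, global_transitivity(gc))
  geo <- geodesic_stats(gc)
  expect_equal(p$geodesic_mean, geo[["geodesic_mean"]])
  expect_equal(p$diameter, geo[["diameter"]])
  expect_equal(p$edges_total, nrow(net$edges))
})

test_that("the summary handles regular and degenerate graphs", {
  p <- network_properties(complete_net(5))
  expect_equal(p$density, 1)
  expect_equal(p$degree_mean, 4)
  expect_equal(p$transitivity, 1)
  expect_equal(p$geodesic_mean, 1)
  expect_equal(p$diameter, 1)
  expect_equal(p$degree_gini, 0)
  expect_equal(p$clustering_gini, 0)
  expect_true(is.na(p$assortativity_edge))            # zero variance: flagged
  expect_true(is.na(p$assortativity_neighbour_mean))
  empty <- sc_network(data.frame(agent_id = integer(0), x = integer(0),
                                 y = integer(0), sr = numeric(0)),
                      matrix(integer(0), ncol = 2))
  expect_error(giant_component(empty), "no agents")
})
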