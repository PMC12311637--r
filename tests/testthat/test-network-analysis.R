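test_that("topology metrics match closed forms on canonical graphs", {
  k3 <- igraph::make_full_graph(3)
  m <- topology_metrics(k3, n_null = 0)
  expect_equal(m$clustering_coefficient, 1)
  expect_equal(m$density, 1)
  expect_equal(m$diameter, 1)
  expect_equal(m$average_degree, 2)

  p4 <- igraph::make_graph(~ a-b, b-c, c-d)
  m4 <- topology_metrics(p4, n_null = 0)
  expect_equal(m4$average_degree, 1.5)
  expect_equal(m4$diameter, 3)

  star <- igraph::make_star(5, mode = "undirected")
  m5 <- topology_metrics(star, n_null = 0)
  expect_equal(m5$degree_centralization, 1)
  expect_error(topology_metrics(igraph::make_empty_graph(1, directed = FALSE)),
               "2 nodes")
})

test_that("keystones are the intersection of top-degree and top-betweenness", {
  star <- igraph::make_star(5, mode = "undirected")  # hub + 4 leaves
  igraph::V(star)$name <- paste0("v", 1:5)
  expect_equal(as.character(keystone_nodes(star)), "v1")

  ring <- igraph::make_ring(8)
  igraph::V(ring)$name <- paste0("r", 1:8)
  expect_setequal(as.character(keystone_nodes(ring)), paste0("r", 1:8))

  # barbell: two K5 joined through a bridge vertex
  g <- igraph::disjoint_union(igraph::make_full_graph(5),
                              igraph::make_full_graph(5))
  g <- igraph::add_vertices(g, 1)
  g <- igraph::add_edges(g, c(1, 11, 6, 11))
  igraph::V(g)$name <- paste0("n", 1:11)
  ks <- keystone_nodes(g, percentile = 80)
  deg <- igraph::degree(g)
  btw_oracle <- betweenness_oracle(g)
  expect_equal(unname(igraph::betweenness(g, weights = NA)), btw_oracle,
               tolerance = 1e-9)
  top_deg <- names(deg)[deg >= sort(deg, decreasing = TRUE)[ceiling(0.2 * 11)]]
  names(btw_oracle) <- igraph::V(g)$name
  top_btw <- names(btw_oracle)[btw_oracle >=
                                 sort(btw_oracle, decreasing = TRUE)[ceiling(0.2 * 11)]]
  expect_setequal(as.character(ks), intersect(top_deg, top_btw))
  # attachment nodes carry all cross-clique traffic
  expect_true(all(c("n1", "n6") %in% ks))
})

test_that("attack robustness matches closed forms exactly where available", {
  k4 <- igraph::make_full_graph(4)
  r4 <- random_attack_robustness(k4, n_iterations = 50, seed = 1)
  expect_equal(r4$R, 3 / 8)       # exact: order-independent for K_N
  expect_equal(r4$V, 1 / 8)
  expect_equal(r4$V + r4$R, 0.5, tolerance = 1e-15)

  e2 <- igraph::make_graph(~ a-b)
  r2 <- random_attack_robustness(e2, n_iterations = 20, seed = 1)
  expect_equal(r2$R, 0.25)
  expect_equal(r2$V, 0.25)
  expect_error(random_attack_robustness(igraph::make_empty_graph(1,
                                                                 directed = FALSE)),
               "2 nodes")
})

test_that("Monte-Carlo robustness agrees with exhaustive enumeration", {
  for (s in 1:3) {
    g <- random_test_graph(6, 0.4, seed = s)
    exact <- robustness_exhaustive(g)
    mc <- random_attack_robustness(g, n_iterations = 4000, seed = s)
    expect_lt(abs(mc$R - exact), 0.005)
    expect_equal(mc$V + mc$R, 0.5, tolerance = 1e-15)
    expect_true(all(diff(mc$sigma) <= 1e-12))  # sigma non-increasing
  }
})

test_that("efficiency matches the Floyd-Warshall oracle and conventions", {
  p3 <- igraph::make_graph(~ a-b, b-c)
  e <- efficiency_distribution(p3)
  expect_equal(unname(e$nodal[c("a", "b", "c")]), c(0.75, 1, 0.75))
  expect_equal(e$mu, 5 / 6, tolerance = 1e-12)

  kc <- igraph::make_full_graph(6)
  expect_true(all(efficiency_distribution(kc)$nodal == 1))

  iso <- igraph::add_vertices(igraph::make_full_graph(4), 1)
  expect_equal(unname(efficiency_distribution(iso)$nodal[5]), 0)

  for (s in 1:10) {
    g <- random_test_graph(sample(5:20, 1), 0.25, seed = 40 + s)
    expect_equal(unname(efficiency_distribution(g)$nodal),
                 efficiency_oracle(g), tolerance = 1e-12)
  }
})

test_that("adding an edge never decreases global efficiency", {
  set.seed(17)
  for (i in 1:20) {
    g <- random_test_graph(10, 0.25, seed = 60 + i)
    non_edges <- which(!adj_matrix(g) & upper.tri(diag(10)), arr.ind = TRUE)
    if (nrow(non_edges) == 0) next
    pick <- non_edges[sample(nrow(non_edges), 1), ]
    g2 <- igraph::add_edges(g, pick)
    expect_gte(efficiency_distribution(g2)$global,
               efficiency_distribution(g)$global - 1e-12)
  }
})
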