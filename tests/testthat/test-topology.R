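# Topological parameters against hand enumeration and brute-force
# matrix oracles.

triangle <- function() {
  make_graph(c("a", "b", "c"), cbind(c("a", "b", "c"), c("b", "c", "a")))
}

test_that("degree profile: chain, isolated node, star", {
  fix <- make_graph(c("a", "b", "c", "z"), cbind(c("a", "b"), c("b", "c")))
  deg <- degree_profile(fix$graph)
  expect_equal(unlist(deg[deg$node == "b", c("gamma_in", "gamma_out", "gamma")]),
               c(gamma_in = 1, gamma_out = 1, gamma = 2))
  expect_equal(deg$gamma[deg$node == "z"], 0)
  expect_equal(sum(deg$gamma), 2 * igraph::ecount(fix$graph))

  star <- make_graph(c("hub", "l1", "l2", "l3", "l4"),
                     cbind(rep("hub", 4), paste0("l", 1:4)))
  dstar <- degree_profile(star$graph)
  expect_equal(unlist(dstar[dstar$node == "hub", 2:4]),
               c(gamma_in = 0, gamma_out = 4, gamma = 4))
})

test_that("clustering: triangle is 1, star is 0", {
  expect_equal(clustering_coefficient(triangle()$graph)$mean, 1.0)
  star <- make_graph(c("h", "a", "b", "c"), cbind(rep("h", 3), c("a", "b", "c")))
  expect_equal(clustering_coefficient(star$graph)$mean, 0)
})

test_that("characteristic path length matches hand enumeration", {
  edge <- make_graph(c("a", "b"), cbind("a", "b"))
  expect_equal(characteristic_path_length(edge$graph), 1.0)
  chain <- make_graph(c("a", "b", "c"), cbind(c("a", "b"), c("b", "c")))
  expect_equal(characteristic_path_length(chain$graph), 4 / 3)
  lonely <- make_graph(c("a", "b"), cbind(character(0), character(0)))
  expect_error(characteristic_path_length(lonely$graph), "no connected pair")
})

test_that("avg neighbors collapses bidirectional links", {
  expect_equal(avg_neighbors(triangle()$graph), 2.0)
  bidir <- make_graph(c("a", "b"), cbind(c("a", "b"), c("b", "a")))
  expect_equal(avg_neighbors(bidir$graph), 1.0)
})

test_that("weak components count the undirected pieces", {
  fix <- make_graph(c("a", "b", "c", "z"),
                    cbind(c("a", "b", "c"), c("b", "c", "a")))
  expect_equal(count_components(fix$graph), 2)
  chain <- make_graph(c("a", "b", "c"), cbind(c("a", "b"), c("b", "c")))
  expect_equal(count_components(chain$graph), 1)
})

test_that("power-law fit recovers exact planted exponents to 1e-9", {
  for (slope in c(-1, -2, -3)) {
    k <- c(1, 2, 4, 8, 16)
    counts <- round(1024 * k^slope)
    degrees <- rep(k, counts)
    fit <- powerlaw_fit(degrees)
    expect_equal(fit$gamma, slope, tolerance = 1e-9)
    expect_equal(fit$r2, 1.0, tolerance = 1e-9)
    expect_equal(fit$r2, fit$r^2, tolerance = 1e-12)
  }
})

test_that("degenerate degree tables are rejected or reported flat", {
  expect_error(powerlaw_fit(rep(5, 50)), "insufficient support")
  expect_error(powerlaw_fit(c(0, 0, 1, 2)), "insufficient support")
  flat <- powerlaw_fit(rep(c(1, 2, 4), each = 5))
  expect_equal(flat$gamma, 0)
  expect_equal(flat$r2, 0)
})

test_that("topology summary assembles the directed-triangle values", {
  s <- topology_summary(triangle()$graph)
  expect_equal(s$n_nodes, 3)
  expect_equal(s$n_links, 3)
  expect_equal(s$n_components, 1)
  expect_equal(s$clustering_coefficient, 1.0)
  expect_equal(s$char_path_length, 1.0)
  expect_error(topology_summary(igraph::make_empty_graph(0, directed = TRUE)),
               "empty")
})

test_that("path length, components and clustering match matrix oracles on random graphs", {
  set.seed(42)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    fix <- random_graph(n, p = stats::runif(1, 0.25, 0.6), connected = FALSE)
    if (all(!is.finite(oracle_distances(fix$adj)[upper.tri(fix$adj)]))) next
    expect_equal(characteristic_path_length(fix$graph), oracle_cpl(fix$adj))
    expect_equal(count_components(fix$graph), oracle_n_components(fix$adj))
    cc <- clustering_coefficient(fix$graph)$per_node
    expect_equal(unname(cc[fix$nodes]), oracle_clustering(fix$adj))
  }
})

test_that("clustering matches the triangle oracle on many small graphs", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(3:6, 1)
    fix <- random_graph(n, p = stats::runif(1, 0.2, 0.9), connected = FALSE)
    cc <- clustering_coefficient(fix$graph)
    expect_equal(unname(cc$per_node[fix$nodes]), oracle_clustering(fix$adj))
    expect_gte(cc$mean, 0); expect_lte(cc$mean, 1)
  }
})
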