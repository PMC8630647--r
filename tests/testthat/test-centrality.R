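# Closeness, normalized betweenness and the shortest-path-tree
# bottleneck score, validated by hand enumeration and by the explicit
# path-walking oracles.

path3 <- function() make_graph(c("a", "b", "c"), cbind(c("a", "b"), c("b", "c")))
star5 <- function() make_graph(c("hub", "l1", "l2", "l3", "l4"),
                               cbind(rep("hub", 4), paste0("l", 1:4)))

test_that("closeness: star center 1, path endpoint 2/3, isolated 0", {
  cl <- closeness_centrality(star5()$graph)
  expect_equal(unname(cl["hub"]), 1.0)
  expect_equal(unname(cl["l1"]), 4 / 7)
  expect_equal(unname(closeness_centrality(path3()$graph, "a")), 2 / 3)
  iso <- make_graph(c("a", "b", "z"), cbind("a", "b"))
  expect_equal(unname(closeness_centrality(iso$graph, "z")), 0)
  expect_error(closeness_centrality(iso$graph, "nope"), "unknown node")
})

test_that("betweenness: path middle 1, star center 1, 4-cycle node 1/6", {
  expect_equal(unname(betweenness_centrality(path3()$graph, "b")), 1.0)
  expect_equal(unname(betweenness_centrality(star5()$graph, "hub")), 1.0)
  cyc <- make_graph(letters[1:4], cbind(c("a", "b", "c", "d"), c("b", "c", "d", "a")))
  expect_equal(unname(betweenness_centrality(cyc$graph)), rep(1 / 6, 4))
  two <- make_graph(c("a", "b"), cbind("a", "b"))
  expect_equal(unname(betweenness_centrality(two$graph)), c(0, 0))
})

test_that("bottleneck score matches the path-walking oracle on hand cases", {
  # single edge: settled by the oracle under the endpoint-counting rule
  two <- make_graph(c("a", "b"), cbind("a", "b"))
  A2 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(oracle_bn(A2, c("a", "b")), c(1L, 1L))
  expect_equal(unname(bottleneck_scores(two$graph)), c(1L, 1L))
  # strict-interior reading excludes the endpoint
  expect_equal(unname(bottleneck_scores(two$graph, count_endpoint = FALSE)),
               c(0L, 0L))
  expect_equal(oracle_bn(A2, c("a", "b"), count_endpoint = FALSE), c(0L, 0L))

  # star center: every leaf-rooted tree routes 4 > 5/4 paths through it
  st <- star5()
  As <- matrix(0, 5, 5); As[1, 2:5] <- 1; As[2:5, 1] <- 1
  expect_equal(unname(bottleneck_scores(st$graph, "hub")), 4L)
  expect_equal(oracle_bn(As, st$nodes)[1], 4L)

  # directed chain: d scores 3 (roots a, b, c) with directed trees,
  # 4 with the undirected projection (root e contributes too)
  ch <- make_graph(letters[1:5], cbind(letters[1:4], letters[2:5]))
  expect_equal(unname(bottleneck_scores(ch$graph, "d", mode = "out")), 3L)
  expect_equal(unname(bottleneck_scores(ch$graph, "d", mode = "all")), 4L)
  Ad <- matrix(0, 5, 5); Ad[cbind(1:4, 2:5)] <- 1
  expect_equal(oracle_bn(Ad, letters[1:5], directed = TRUE)[4], 3L)
})

test_that("centralities match the brute-force oracles on 200 random connected graphs", {
  set.seed(1234)
  for (i in 1:200) {
    n <- sample(4:10, 1)
    fix <- random_graph(n, p = stats::runif(1, 0.3, 0.7))
    cl <- closeness_centrality(fix$graph)
    bw <- betweenness_centrality(fix$graph)
    bn <- bottleneck_scores(fix$graph)
    expect_equal(unname(cl[fix$nodes]), oracle_closeness(fix$adj))
    expect_equal(unname(bw[fix$nodes]), oracle_betweenness(fix$adj),
                 tolerance = 1e-12)
    expect_identical(unname(bn[fix$nodes]), oracle_bn(fix$adj, fix$nodes))
    expect_true(all(cl >= 0 & cl <= 1))
    expect_true(all(bw >= 0 & bw <= 1))
    expect_true(all(bn >= 0 & bn <= n - 1 & bn == as.integer(bn)))
  }
})

test_that("centralities are label-invariant under node permutation", {
  set.seed(99)
  fix <- random_graph(8, p = 0.4)
  perm_names <- stats::setNames(sample(paste0("x", 1:8)), fix$nodes)
  g2 <- fix$graph
  igraph::V(g2)$name <- unname(perm_names[igraph::V(fix$graph)$name])
  for (fun in list(closeness_centrality, betweenness_centrality)) {
    v1 <- fun(fix$graph)
    v2 <- fun(g2)
    expect_equal(unname(v2[unname(perm_names[names(v1)])]), unname(v1))
  }
})

test_that("reverse-lexicographic tree choice is a recorded sensitivity, not an error", {
  set.seed(5)
  fix <- random_graph(9, p = 0.45)
  lex <- bottleneck_scores(fix$graph, neighbor_order = "lex")
  rev <- bottleneck_scores(fix$graph, neighbor_order = "revlex")
  expect_true(all(rev >= 0))
  expect_equal(length(lex), length(rev))  # scores may differ; both defined
})

test_that("the centrality table is complete and deterministic", {
  net <- synthetic_database(synthetic_spec(n_nodes = 40, target_edges = 90,
                                           seed = 2))$network
  t1 <- all_centralities(net)
  t2 <- all_centralities(net)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 40)
  expect_true(all(c("node", "gamma_in", "gamma_out", "gamma", "closeness",
                    "betweenness", "bn_score") %in% names(t1)))
})
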