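# Targeted versus random node removal and collapse detection.

test_that("removing a star's center shatters it", {
  star <- make_graph(c("hub", "l1", "l2", "l3", "l4"),
                     cbind(rep("hub", 4), paste0("l", 1:4)))
  a <- targeted_attack(star$graph, fraction = 0.2, cycles = 1)
  expect_equal(a$removed[[1]], "hub")
  expect_equal(a$giant_fraction, 1 / 5)
  expect_true(a$collapsed)
  expect_length(a$trajectory, 2)
})

test_that("attack parameter validation", {
  ch <- make_graph(c("a", "b", "c"), cbind(c("a", "b"), c("b", "c")))
  expect_error(targeted_attack(ch$graph, fraction = 0), "fraction")
  expect_error(targeted_attack(ch$graph, fraction = 1.2), "fraction")
  expect_error(random_attack(ch$graph, n_per_cycle = 0, cycles = 1, seed = 1),
               "zero nodes")
  expect_error(random_attack(ch$graph, n_per_cycle = 5, cycles = 1, seed = 1),
               "cannot remove")
  expect_error(random_attack(ch$graph, n_per_cycle = 1, cycles = 1),
               "seed is mandatory")
})

test_that("random attacks with the same seed are bit-reproducible", {
  net <- synthetic_database(synthetic_spec(n_nodes = 80, target_edges = 200,
                                           seed = 10))$network
  a1 <- random_attack(net, n_per_cycle = 3, cycles = 2, seed = 7)
  a2 <- random_attack(net, n_per_cycle = 3, cycles = 2, seed = 7)
  expect_identical(a1$removed, a2$removed)
  expect_identical(a1$giant_fraction, a2$giant_fraction)
  t1 <- targeted_attack(net, fraction = 0.05, cycles = 2)
  t2 <- targeted_attack(net, fraction = 0.05, cycles = 2)
  expect_identical(t1$removed, t2$removed)
})

test_that("node count strictly decreases and trajectories have cycles+1 entries", {
  net <- synthetic_database(synthetic_spec(n_nodes = 100, target_edges = 260,
                                           seed = 2))$network
  a <- targeted_attack(net, fraction = 0.1, cycles = 3)
  n_seq <- vapply(a$trajectory, function(s) s$n_nodes, numeric(1))
  expect_length(n_seq, 4)
  expect_true(all(diff(n_seq) < 0))
})

test_that("collapse detection fires on shattering and stays quiet on nothing", {
  star <- make_graph(c("hub", paste0("l", 1:9)),
                     cbind(rep("hub", 9), paste0("l", 1:9)))
  before <- topology_summary(star$graph, allow_degenerate = TRUE)
  leaves <- igraph::delete_vertices(star$graph, "hub")
  after <- topology_summary(leaves, allow_degenerate = TRUE)
  verdict <- detect_collapse(before, after, giant_fraction = 0.1)
  expect_true(verdict$collapsed)
  expect_match(paste(verdict$reasons, collapse = "; "), "giant component")
  same <- detect_collapse(before, before, giant_fraction = 1.0)
  expect_false(same$collapsed)
})

test_that("targeted attack damages scale-free networks more than matched random attack", {
  wins <- 0
  for (seed in 1:6) {
    net <- generate_layered_scalefree(synthetic_spec(n_nodes = 500,
                                                     target_edges = 1625,
                                                     seed = seed))$network
    tgt <- targeted_attack(net, fraction = 0.025, cycles = 2)
    rnd <- random_attack(net, n_per_cycle = lengths(tgt$removed), cycles = 2,
                         seed = seed + 1000)
    if (tail(tgt$giant_fraction, 1) < tail(rnd$giant_fraction, 1)) wins <- wins + 1
  }
  expect_gte(wins, 5)   # the full 20-seed paired comparison runs in the
                        # acceptance suite
})

test_that("the targeted-vs-random gap is much smaller on an Erdos-Renyi control", {
  gap <- function(g) {
    net <- signaling_network(g)
    tgt <- targeted_attack(net, fraction = 0.05, cycles = 2)
    rnd <- random_attack(net, n_per_cycle = lengths(tgt$removed), cycles = 2,
                         seed = 11)
    tail(rnd$giant_fraction, 1) - tail(tgt$giant_fraction, 1)
  }
  gaps_ba <- gaps_er <- numeric(10)
  for (seed in 1:10) {
    ba <- generate_layered_scalefree(synthetic_spec(n_nodes = 300,
                                                    target_edges = 900,
                                                    seed = seed))$network
    gaps_ba[seed] <- gap(ba$graph)
    set.seed(seed)
    er <- igraph::sample_gnm(300, 900, directed = TRUE)
    igraph::V(er)$name <- sprintf("e%03d", 1:300)
    gaps_er[seed] <- gap(er)
  }
  expect_gt(mean(gaps_ba), 2 * mean(gaps_er))
})
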