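# Reading, validating and exporting curated interaction tables, and
# construction of the directed simple network.

write_table <- function(rows, header = "Source molecule\tInteraction\tTarget molecule\tSpecies\tPMID") {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(header, rows), path)
  path
}

test_that("a well-formed table parses to one record per row", {
  path <- write_table(c(
    "FSH\tactivates\tFSHR\tRodent\t11111111",
    "LH\tinhibits\tAMH\tOvine\t22222222",
    "KL\tinduces\tfollicle activation\tBovine\t33333333"
  ))
  db <- read_interaction_table(path)
  expect_s3_class(db, "interaction_db")
  expect_equal(nrow(db$records), 3)
  expect_equal(db$records$source, c("FSH", "LH", "KL"))
  expect_equal(db$records$target[3], "follicle activation")
  expect_equal(db$n_skipped, 0)
  expect_equal(db$n_duplicates_dropped, 0)
})

test_that("duplicate rows collapse and empty endpoints are skipped, with counts", {
  path <- write_table(c(
    "FSH\tactivates\tFSHR\tRodent\t11111111",
    "FSH\tactivates\tFSHR\tRodent\t11111111",
    "LH\tactivates\t\tRodent\t22222222"
  ))
  expect_message(expect_message(db <- read_interaction_table(path),
                                "1 exact duplicate"),
                 "skipped 1 record")
  expect_equal(nrow(db$records), 1)
  expect_equal(db$n_duplicates_dropped, 1)
  expect_equal(db$n_skipped, 1)
})

test_that("whitespace is canonicalized before identity checks", {
  path <- write_table(c(
    "FSH \tactivates\t FSHR\tRodent\t11111111",
    "FSH\tactivates\tFSHR \tRodent\t11111111"
  ))
  db <- suppressMessages(read_interaction_table(path))
  expect_equal(nrow(db$records), 1)
  expect_equal(canonicalize_name("  a   b \t c "), "a b c")
})

test_that("a table without a source or target column is rejected", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("Interaction\tSpecies\tPMID", "activates\tRodent\t1"), path)
  expect_error(read_interaction_table(path), "source and a target column")
})

test_that("non-numeric PMIDs are treated as absent", {
  db <- interaction_db(data.frame(
    source = c("a", "b"), interaction = "activates", target = c("b", "c"),
    species = "Rodent", pmid = c("12345", "PMC999")))
  expect_equal(db$records$pmid, c("12345", NA))
})

test_that("species incidence is a percentage table summing to 100", {
  rec <- data.frame(source = paste0("s", 1:100), interaction = "activates",
                    target = paste0("t", 1:100),
                    species = c(rep("Rodent", 39), rep("Ovine", 61)),
                    pmid = sprintf("%08d", 1:100))
  inc <- species_incidence(interaction_db(rec))
  expect_equal(inc$percent[inc$species == "Rodent"], 39.00)
  expect_equal(sum(inc$percent), 100, tolerance = 0.0005)

  one <- species_incidence(interaction_db(data.frame(
    source = "a", interaction = "binds", target = "b",
    species = "Ovine", pmid = "1")))
  expect_equal(one$percent, 100.00)
  expect_error(species_incidence(interaction_db(rec[0, ])), "no records")
})

test_that("build_network collapses parallel records, keeps direction, drops loops", {
  db <- interaction_db(data.frame(
    source = c("a", "a", "b", "c"), interaction = c("activates", "inhibits", "binds", "binds"),
    target = c("b", "b", "a", "c"), species = "Rodent",
    pmid = c("1", "2", "3", "4")))
  net <- suppressMessages(build_network(db))
  g <- net$graph
  expect_equal(igraph::ecount(g), 2)           # a->b collapsed, b->a kept, c->c dropped
  eid <- igraph::get_edge_ids(g, c("a", "b"))
  expect_equal(igraph::E(g)$pmid[eid], "1|2")
  expect_equal(igraph::E(g)$interaction[eid], "activates|inhibits")
  expect_true(igraph::are_adjacent(g, "b", "a"))
  expect_equal(net$counts$loops_dropped, 1)
  expect_true("c" %in% igraph::V(g)$name)      # loop-only node kept, isolated
  expect_error(build_network(interaction_db(db$records[0, ])), "empty")
})

test_that("SIF export writes source<TAB>interaction<TAB>target", {
  db <- interaction_db(data.frame(source = "a", interaction = "activates",
                                  target = "b", species = "Rodent", pmid = "1"))
  net <- build_network(db)
  path <- tempfile(fileext = ".sif")
  export_network(net, path, "sif")
  expect_equal(readLines(path), "a\tactivates\tb")
  expect_error(export_network(net, path, "dot"), "sif, graphml, edgelist")
  empty <- signaling_network(igraph::make_empty_graph(1, directed = TRUE))
  expect_error(export_network(empty, path, "sif"), "empty")
})

test_that("round-trips through every format preserve node and edge sets", {
  spec <- synthetic_spec(n_nodes = 30, target_edges = 60, seed = 4)
  net <- synthetic_database(spec)$network
  for (fmt in c("sif", "graphml", "edgelist")) {
    path <- tempfile()
    export_network(net, path, fmt)
    back <- read_network(path, fmt)
    expect_setequal(igraph::V(back$graph)$name, igraph::V(net$graph)$name)
    expect_setequal(apply(igraph::as_edgelist(back$graph), 1, paste, collapse = ">"),
                    apply(igraph::as_edgelist(net$graph), 1, paste, collapse = ">"))
  }
})

test_that("building from a re-read exported table is idempotent", {
  spec <- synthetic_spec(n_nodes = 25, target_edges = 50, seed = 9)
  gen <- synthetic_database(spec)
  path <- tempfile(fileext = ".tsv")
  write_interaction_table(gen$db, path)
  net2 <- build_network(read_interaction_table(path))
  expect_setequal(igraph::V(net2$graph)$name, igraph::V(gen$network$graph)$name)
  expect_equal(igraph::ecount(net2$graph), igraph::ecount(gen$network$graph))
  # size bounds relative to the record table
  expect_lte(igraph::ecount(net2$graph), nrow(gen$db$records))
  expect_lte(igraph::vcount(net2$graph), 2 * nrow(gen$db$records))
})
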