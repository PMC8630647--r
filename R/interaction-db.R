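#' @importFrom stats aggregate
NULL

#' Canonicalize molecule / label names
#'
#' Trims leading and trailing whitespace and collapses internal runs of
#' whitespace to a single space. Case is preserved: node identity in a
#' curated database is the curated name string, and no synonym resolution
#' is attempted.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @export
canonicalize_name <- function(x) {
  x <- gsub("[[:space:]]+", " ", as.character(x))
  trimws(x)
}

# Map a header to the five canonical fields, case-insensitively.
# Accepts the common curated-table variants ("Source molecule", "Reference").
.match_db_columns <- function(header) {
  h <- tolower(trimws(header))
  pick <- function(patterns) {
    for (p in patterns) {
      i <- which(grepl(p, h))
      if (length(i)) return(i[1L])
    }
    NA_integer_
  }
  c(
    source      = pick(c("^source", "source")),
    interaction = pick(c("^interaction$", "interaction")),
    target      = pick(c("^target", "target")),
    species     = pick(c("^species$", "species", "mammal")),
    pmid        = pick(c("^pmid$", "pmid", "reference"))
  )
}

#' Read a curated interaction table
#'
#' Reads a delimited text file with one literature-curated interaction per
#' row and (at least) the five fields *source*, *interaction*, *target*,
#' *species* and *pmid* (header matched case-insensitively; `reference`
#' is accepted for the PMID column). Rows whose source or target is empty
#' after canonicalization are skipped; exact duplicates on all five fields
#' are collapsed. Both counts are reported via [message()] and stored on
#' the returned object.
#'
#' @param path path to the delimited file (UTF-8, header row required).
#' @param delimiter field delimiter; default tab, `","` accepted.
#' @return an `interaction_db` object: a list with elements
#'   `records` (data.frame with columns source, interaction, target,
#'   species, pmid), `provenance` (description + source path),
#'   `n_duplicates_dropped`, and `n_skipped`.
#' @export
read_interaction_table <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("interaction table not found: ", path)
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  idx <- .match_db_columns(names(raw))
  if (is.na(idx[["source"]]) || is.na(idx[["target"]])) {
    stop("interaction table must name both a source and a target column; ",
         "found: ", paste(names(raw), collapse = ", "))
  }
  get_col <- function(name) {
    i <- idx[[name]]
    if (is.na(i)) rep(NA_character_, nrow(raw)) else raw[[i]]
  }
  rec <- data.frame(
    source      = canonicalize_name(get_col("source")),
    interaction = canonicalize_name(get_col("interaction")),
    target      = canonicalize_name(get_col("target")),
    species     = canonicalize_name(get_col("species")),
    pmid        = canonicalize_name(get_col("pmid")),
    stringsAsFactors = FALSE
  )
  interaction_db(rec, provenance = list(description = "read from file",
                                        path = path))
}

#' Construct an interaction database from a record data frame
#'
#' Validates and canonicalizes records: empty-endpoint rows are skipped,
#' non-numeric PMIDs are blanked (a PMID is a digit string or absent),
#' and exact duplicates on (source, interaction, target, species, pmid)
#' are collapsed.
#'
#' @param records data.frame with columns source, interaction, target,
#'   species, pmid (missing annotation columns are filled with `NA`).
#' @param provenance free-form list describing where the records came from.
#' @return an `interaction_db` object.
#' @export
interaction_db <- function(records, provenance = list(description = "in-memory")) {
  for (col in c("interaction", "species", "pmid")) {
    if (is.null(records[[col]])) records[[col]] <- NA_character_
  }
  records <- records[, c("source", "interaction", "target", "species", "pmid")]
  for (col in names(records)) records[[col]] <- canonicalize_name(records[[col]])

  bad <- is.na(records$source) | records$source == "" |
    is.na(records$target) | records$target == ""
  n_skipped <- sum(bad)
  if (n_skipped > 0) {
    message("skipped ", n_skipped, " record(s) with empty source or target")
    records <- records[!bad, , drop = FALSE]
  }
  # PMIDs are digit strings; anything else is treated as absent
  bad_pmid <- !is.na(records$pmid) & records$pmid != "" &
    !grepl("^[0-9]+$", records$pmid)
  records$pmid[bad_pmid | records$pmid %in% ""] <- NA_character_

  key <- do.call(paste, c(lapply(records, function(x) ifelse(is.na(x), "\r", x)),
                          sep = "\x1f"))
  dup <- duplicated(key)
  n_dup <- sum(dup)
  if (n_dup > 0) {
    message("collapsed ", n_dup, " exact duplicate record(s)")
    records <- records[!dup, , drop = FALSE]
  }
  rownames(records) <- NULL
  structure(
    list(records = records, provenance = provenance,
         n_duplicates_dropped = n_dup, n_skipped = n_skipped),
    class = "interaction_db"
  )
}

#' @export
print.interaction_db <- function(x, ...) {
  cat("Curated interaction database: ", nrow(x$records), " records\n", sep = "")
  cat("  duplicates collapsed: ", x$n_duplicates_dropped,
      ", rows skipped: ", x$n_skipped, "\n", sep = "")
  invisible(x)
}

#' Species incidence of a curated database
#'
#' Percentage of interaction records attributed to each mammal model,
#' reported to two decimals and sorted by decreasing share.
#'
#' @param db an `interaction_db`.
#' @return data.frame with columns `species` and `percent`
#'   (percentages sum to 100 within rounding).
#' @export
species_incidence <- function(db) {
  stopifnot(inherits(db, "interaction_db"))
  rec <- db$records
  if (nrow(rec) == 0) stop("no records")
  sp <- rec$species
  sp[is.na(sp) | sp == ""] <- "Unspecified"
  tab <- sort(table(sp), decreasing = TRUE)
  out <- data.frame(
    species = names(tab),
    percent = round(100 * as.numeric(tab) / nrow(rec), 2),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Build the directed signaling network from a database
#'
#' One directed edge per distinct ordered (source, target) pair.
#' Interaction labels, species and PMIDs of all contributing records are
#' merged onto the edge (pipe-separated, order preserved). Self-loops
#' are dropped (their count is reported): the path-based topology and
#' centrality metrics used downstream are undefined on loops. Parallel
#' edges are collapsed network-wide so that betweenness, which requires a
#' simple graph, and the single reported link count are both well defined.
#'
#' @param db an `interaction_db` with at least one record.
#' @return a `signaling_network`: a list with the directed simple
#'   [igraph::graph] in `$graph` (edge attributes `interaction`,
#'   `species`, `pmid`) and build bookkeeping in `$counts`
#'   (`records_in`, `edges_out`, `loops_dropped`).
#' @export
build_network <- function(db) {
  stopifnot(inherits(db, "interaction_db"))
  rec <- db$records
  if (nrow(rec) == 0) stop("cannot build a network from an empty database")

  loops <- rec$source == rec$target
  n_loops <- sum(loops)
  if (n_loops > 0) message("dropped ", n_loops, " self-loop record(s)")
  all_nodes <- sort(unique(c(rec$source, rec$target)))
  rec <- rec[!loops, , drop = FALSE]

  key <- paste(rec$source, rec$target, sep = "\x1f")
  merge_attr <- function(x) {
    vapply(split(x, key)[unique(key)],
           function(v) paste(ifelse(is.na(v), "", v), collapse = "|"),
           character(1))
  }
  first <- !duplicated(key)
  edges <- data.frame(
    from = rec$source[first],
    to = rec$target[first],
    interaction = unname(merge_attr(rec$interaction)),
    species = unname(merge_attr(rec$species)),
    pmid = unname(merge_attr(rec$pmid)),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = all_nodes))
  signaling_network(g, counts = list(records_in = nrow(db$records),
                                     edges_out = nrow(edges),
                                     loops_dropped = n_loops))
}

#' Wrap an igraph graph as a signaling network
#'
#' Enforces the structural invariants of the analysis substrate: directed,
#' no self-loops, no parallel edges, named vertices.
#'
#' @param graph a directed [igraph::graph] with a `name` vertex attribute.
#' @param counts optional build bookkeeping list.
#' @return a `signaling_network` object.
#' @export
signaling_network <- function(graph, counts = list()) {
  stopifnot(igraph::is_directed(graph))
  if (is.null(igraph::V(graph)$name)) {
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  }
  if (igraph::any_loop(graph) || igraph::any_multiple(graph)) {
    graph <- igraph::simplify(graph, remove.multiple = TRUE,
                              remove.loops = TRUE,
                              edge.attr.comb = function(x) paste(x, collapse = "|"))
  }
  structure(list(graph = graph, counts = counts), class = "signaling_network")
}

# Accept either a signaling_network or a bare igraph everywhere downstream.
as_graph <- function(net) {
  if (inherits(net, "signaling_network")) return(net$graph)
  if (igraph::is_igraph(net)) return(net)
  stop("expected a signaling_network or an igraph object")
}

# Undirected simple projection: the metric space for distance-based
# measures (clustering, path length, neighbors, components, centralities).
undirected_projection <- function(net) {
  g <- as_graph(net)
  igraph::simplify(igraph::as_undirected(g, mode = "collapse"),
                   remove.multiple = TRUE, remove.loops = TRUE)
}

#' @export
print.signaling_network <- function(x, ...) {
  g <- x$graph
  cat("Signaling network: ", igraph::vcount(g), " nodes, ",
      igraph::ecount(g), " directed links\n", sep = "")
  if (length(x$counts)) {
    cat("  built from ", x$counts$records_in, " records (",
        x$counts$loops_dropped, " self-loops dropped)\n", sep = "")
  }
  invisible(x)
}

#' Export a signaling network to an interchange format
#'
#' `sif` writes `source<TAB>interaction<TAB>target` using the first
#' interaction label on each edge; `graphml` carries the merged
#' interaction/species/pmid annotations as edge attributes; `edgelist`
#' is a two-column TSV (with header `source`/`target`).
#'
#' @param net a `signaling_network` (non-empty).
#' @param path output file path.
#' @param format one of `"sif"`, `"graphml"`, `"edgelist"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("sif", "graphml", "edgelist")) {
  format <- tryCatch(match.arg(format),
                     error = function(e)
                       stop("unknown format; supported: sif, graphml, edgelist"))
  g <- as_graph(net)
  if (igraph::ecount(g) == 0) stop("refusing to export an empty network")
  el <- igraph::as_edgelist(g, names = TRUE)
  if (format == "sif") {
    lab <- igraph::E(g)$interaction
    if (is.null(lab)) lab <- rep("interacts", nrow(el))
    lab <- vapply(strsplit(lab, "|", fixed = TRUE),
                  function(x) if (length(x) && nzchar(x[1])) x[1] else "interacts",
                  character(1))
    writeLines(paste(el[, 1], lab, el[, 2], sep = "\t"), path)
  } else if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    utils::write.table(data.frame(source = el[, 1], target = el[, 2]),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a network back from an interchange file
#'
#' Inverse of [export_network()]; round-tripping preserves node and edge
#' sets (SIF/edgelist exports drop isolated nodes, which have no row).
#'
#' @param path file written by [export_network()].
#' @param format one of `"sif"`, `"graphml"`, `"edgelist"`.
#' @return a `signaling_network`.
#' @export
read_network <- function(path, format = c("sif", "graphml", "edgelist")) {
  format <- tryCatch(match.arg(format),
                     error = function(e)
                       stop("unknown format; supported: sif, graphml, edgelist"))
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    return(signaling_network(g))
  }
  if (format == "sif") {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, quote = "")
    rec <- data.frame(source = tab[[1]], interaction = tab[[2]],
                      target = tab[[3]], stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, quote = "")
    rec <- data.frame(source = tab[[1]], interaction = NA_character_,
                      target = tab[[2]], stringsAsFactors = FALSE)
  }
  build_network(interaction_db(rec, provenance = list(description = "re-imported",
                                                      path = path)))
}

#' Write an interaction database as a five-column TSV
#'
#' @param db an `interaction_db`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(db, path) {
  stopifnot(inherits(db, "interaction_db"))
  utils::write.table(db$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
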