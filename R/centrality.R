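# Node centralities: closeness, normalized betweenness, and the
# shortest-path-tree bottleneck score. The default metric space is the
# undirected simple projection (mode = "all"), consistent with the
# topology module; mode = "out" computes directed variants.

.metric_graph <- function(net, mode) {
  if (mode == "all") undirected_projection(net) else as_graph(net)
}

.check_nodes <- function(g, nodes) {
  if (is.null(nodes)) return(igraph::V(g)$name)
  missing <- setdiff(nodes, igraph::V(g)$name)
  if (length(missing)) stop("unknown node(s): ", paste(missing, collapse = ", "))
  nodes
}

#' Closeness centrality
#'
#' Reciprocal of the mean shortest-path length from a node to every node
#' it can reach; isolated nodes (no reachable node) score 0. Values lie
#' in \[0, 1\], with 1 for a node at distance 1 from everything it reaches.
#'
#' @param net a `signaling_network` or igraph.
#' @param nodes node names (default: all nodes).
#' @param mode `"all"` (undirected projection, default) or `"out"`
#'   (directed distances).
#' @return named numeric vector of closeness values.
#' @export
closeness_centrality <- function(net, nodes = NULL, mode = c("all", "out")) {
  mode <- match.arg(mode)
  g <- .metric_graph(net, mode)
  nodes <- .check_nodes(g, nodes)
  d <- igraph::distances(g, v = nodes, mode = "out")
  self <- cbind(seq_along(nodes), match(nodes, colnames(d)))
  d[self] <- Inf
  out <- apply(d, 1, function(row) {
    r <- row[is.finite(row)]
    if (length(r) == 0) 0 else 1 / mean(r)
  })
  stats::setNames(as.numeric(out), nodes)
}

#' Betweenness centrality (normalized)
#'
#' Fraction of shortest paths between other node pairs that pass through
#' a node, normalized by the number of node pairs excluding it within its
#' connected component: (N-1)(N-2)/2 for the undirected default
#' (unordered pairs), (N-1)(N-2) for directed distances (ordered pairs).
#' Values lie in \[0, 1\]. Requires a simple graph, which
#' [build_network()] guarantees.
#'
#' @inheritParams closeness_centrality
#' @return named numeric vector of normalized betweenness values.
#' @export
betweenness_centrality <- function(net, nodes = NULL, mode = c("all", "out")) {
  mode <- match.arg(mode)
  g <- .metric_graph(net, mode)
  all_nodes <- igraph::V(g)$name
  nodes <- .check_nodes(g, nodes)
  b <- igraph::betweenness(g, directed = (mode == "out"), weights = NULL)
  comp <- igraph::components(g, mode = "weak")
  N <- comp$csize[comp$membership]
  norm <- if (mode == "all") (N - 1) * (N - 2) / 2 else (N - 1) * (N - 2)
  val <- ifelse(norm > 0, b / norm, 0)
  stats::setNames(as.numeric(val), all_nodes)[nodes]
}

# Shortest-path trees for every root, with a deterministic parent rule:
# breadth-first layers come from exact distances; the parent of v is its
# neighbor u one layer closer with the smallest (or largest, for the
# sensitivity check) lexicographic rank. Returns the per-root loop as a
# closure so bottleneck_scores and its tests share one traversal.
.bn_machinery <- function(g, neighbor_order) {
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  rk <- rank(nm, ties.method = "first")
  if (neighbor_order == "revlex") rk <- n + 1 - rk
  el <- igraph::as_edgelist(g, names = FALSE)
  list(n = n, nm = nm, rk = rk, eu = el[, 1], ev = el[, 2])
}

#' Bottleneck (BN) score
#'
#' For every root node s, one shortest-path tree Ts is built (parent =
#' lexicographically first neighbor in the previous breadth-first layer).
#' A vertex v is a local bottleneck for s — ps(v) = 1 — when more than
#' |V(Ts)|/4 of the tree paths from s to the other tree nodes meet at v;
#' with the subtree-size reading used here (the path endpoint counts as
#' meeting its own path, `count_endpoint = TRUE`) that count is exactly
#' the size of the subtree rooted at v. The bottleneck score is
#' BN(v) = sum over roots s of ps(v).
#'
#' @inheritParams closeness_centrality
#' @param neighbor_order `"lex"` (default) or `"revlex"`; the
#'   deterministic parent tie-break, exposed so the sensitivity of BN to
#'   the tree choice can be measured.
#' @param count_endpoint if `FALSE`, a path is counted as meeting v only
#'   when v is interior to it (the strict reading).
#' @return named integer vector of BN scores (0 <= BN(v) <= n - 1).
#' @export
bottleneck_scores <- function(net, nodes = NULL, mode = c("all", "out"),
                              neighbor_order = c("lex", "revlex"),
                              count_endpoint = TRUE) {
  mode <- match.arg(mode)
  neighbor_order <- match.arg(neighbor_order)
  g <- .metric_graph(net, mode)
  nodes <- .check_nodes(g, nodes)
  mc <- .bn_machinery(g, neighbor_order)
  n <- mc$n
  if (mode == "all") {
    eu <- c(mc$eu, mc$ev); ev <- c(mc$ev, mc$eu)
  } else {
    eu <- mc$eu; ev <- mc$ev
  }
  D <- igraph::distances(g, mode = "out")
  bn <- rep(0L, n)
  for (s in seq_len(n)) {
    ds <- D[s, ]
    reached <- which(is.finite(ds))
    nt <- length(reached)            # |V(Ts)| including the root
    if (nt < 2) next
    cand <- which(is.finite(ds[eu]) & ds[eu] + 1 == ds[ev])
    if (!length(cand)) next
    cu <- eu[cand]; cv <- ev[cand]
    o <- order(cv, mc$rk[cu])
    cu <- cu[o]; cv <- cv[o]
    keep <- !duplicated(cv)
    father <- rep(NA_integer_, n)
    father[cv[keep]] <- cu[keep]
    size <- rep(1L, n)
    ord <- reached[reached != s]
    ord <- ord[order(-ds[ord])]
    for (v in ord) {
      f <- father[v]
      size[f] <- size[f] + size[v]
    }
    cnt <- size[ord]
    if (!count_endpoint) cnt <- cnt - 1L
    hit <- ord[cnt > nt / 4]
    bn[hit] <- bn[hit] + 1L
  }
  stats::setNames(bn, mc$nm)[nodes]
}

#' All node centralities in one table
#'
#' Degrees, closeness, normalized betweenness and bottleneck score for
#' every node; deterministic across runs.
#'
#' @inheritParams closeness_centrality
#' @return data.frame with columns `node`, `gamma_in`, `gamma_out`,
#'   `gamma`, `closeness`, `betweenness`, `bn_score`.
#' @export
all_centralities <- function(net, mode = c("all", "out")) {
  mode <- match.arg(mode)
  g <- as_graph(net)
  if (igraph::vcount(g) == 0) stop("empty network")
  deg <- degree_profile(g)
  deg$closeness <- unname(closeness_centrality(g, nodes = deg$node, mode = mode))
  deg$betweenness <- unname(betweenness_centrality(g, nodes = deg$node, mode = mode))
  deg$bn_score <- unname(bottleneck_scores(g, nodes = deg$node, mode = mode))
  deg
}
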