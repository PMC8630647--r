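# Controllers: degree hubs, shortest-path-tree bottlenecks, and their
# intersection (hub.BN) — the small set of nodes that steer the network.

#' Identify hubs by the mean-plus-one-standard-deviation rule
#'
#' A node is a hub when its total degree strictly exceeds mu + sigma,
#' where mu is the mean and sigma the population (divide-by-n) standard
#' deviation of total degree over all nodes. In a scale-free network this
#' singles out the hyperconnected minority.
#'
#' @param degrees named numeric vector of total degrees (>= 2 nodes).
#' @return list with `hubs` (character vector of node names, ordered by
#'   decreasing degree then name) and `threshold` (list `mu`, `sigma`,
#'   `threshold`).
#' @export
identify_hubs <- function(degrees) {
  if (length(degrees) < 2) stop("need at least 2 nodes to define a hub threshold")
  if (is.null(names(degrees))) stop("degrees must be a named vector")
  mu <- mean(degrees)
  sigma <- sqrt(mean((degrees - mu)^2))
  thr <- mu + sigma
  hub <- degrees > thr
  nm <- names(degrees)[hub]
  nm <- nm[order(-degrees[hub], nm)]
  list(hubs = nm,
       threshold = list(mu = mu, sigma = sigma, threshold = thr))
}

#' Identify bottleneck nodes as the top-k by BN score
#'
#' Ties at the cutoff are broken by higher total degree, then by
#' lexicographic node name, so the selection is deterministic.
#'
#' @param bn_scores named numeric vector of bottleneck scores.
#' @param k number of bottlenecks to keep (the tool convention is a
#'   user-chosen top-N; the pipeline defaults it to the hub count).
#' @param degrees optional named total-degree vector for the tie-break.
#' @return character vector of the k selected node names.
#' @export
identify_bottlenecks <- function(bn_scores, k, degrees = NULL) {
  if (k < 0) stop("k must be >= 0")
  if (k > length(bn_scores)) stop("k exceeds the number of nodes")
  if (k == 0) return(character(0))
  nm <- names(bn_scores)
  deg <- if (is.null(degrees)) stats::setNames(rep(0, length(nm)), nm) else degrees[nm]
  o <- order(-bn_scores, -deg, nm)
  nm[o][seq_len(k)]
}

#' Intersect hubs and bottlenecks into the controller set
#'
#' The hub.BN nodes — hubs that are also bottlenecks — are the network's
#' controllers; the union of both sets, as a share of the network, gives
#' the controller percentage.
#'
#' @param hubs character vector of hub names (with a `threshold`
#'   attribute-style list accepted from [identify_hubs()]).
#' @param bottlenecks character vector of bottleneck names.
#' @param n_nodes total node count of the network the sets came from.
#' @param threshold optional hub threshold bookkeeping to carry along.
#' @return a `controller_set`: list with `hubs`, `bottlenecks`, `hub_bn`,
#'   `threshold`, `k_bottlenecks`, `n_nodes`, and the derived
#'   `hub_percent`, `bn_percent`, `union_percent`.
#' @export
intersect_controllers <- function(hubs, bottlenecks, n_nodes,
                                  threshold = NULL) {
  if (is.list(hubs) && !is.null(hubs$hubs)) {
    threshold <- hubs$threshold
    hubs <- hubs$hubs
  }
  hub_bn <- intersect(hubs, bottlenecks)
  n_union <- length(union(hubs, bottlenecks))
  structure(list(
    hubs = hubs,
    bottlenecks = bottlenecks,
    hub_bn = hub_bn,
    threshold = threshold,
    k_bottlenecks = length(bottlenecks),
    n_nodes = n_nodes,
    hub_percent = 100 * length(hubs) / n_nodes,
    bn_percent = 100 * length(bottlenecks) / n_nodes,
    union_percent = 100 * n_union / n_nodes
  ), class = "controller_set")
}

#' @export
print.controller_set <- function(x, ...) {
  cat(sprintf("Controllers of a %d-node network\n", x$n_nodes))
  cat(sprintf("  hubs:        %d (%.1f%%)", length(x$hubs), x$hub_percent))
  if (!is.null(x$threshold)) {
    cat(sprintf("  [degree > mu + sigma = %.2f + %.2f = %.2f]",
                x$threshold$mu, x$threshold$sigma, x$threshold$threshold))
  }
  cat("\n")
  cat(sprintf("  bottlenecks: %d (top-%d by BN score)\n",
              length(x$bottlenecks), x$k_bottlenecks))
  cat(sprintf("  hub.BN:      %d; controller union %.1f%% of the network\n",
              length(x$hub_bn), x$union_percent))
  invisible(x)
}

#' Identify the full controller set of a network
#'
#' Convenience wrapper: computes total degrees and BN scores, applies the
#' hub rule, takes the top-k bottlenecks (k defaults to the hub count,
#' reproducing the matched-count convention), and intersects.
#'
#' @param net a `signaling_network` or igraph.
#' @param k_bottlenecks bottleneck count; default `NULL` means "as many
#'   as there are hubs".
#' @param mode metric space for the BN score, see [bottleneck_scores()].
#' @return a `controller_set`.
#' @export
find_controllers <- function(net, k_bottlenecks = NULL, mode = "all") {
  g <- as_graph(net)
  deg <- igraph::degree(g, mode = "all")
  h <- identify_hubs(deg)
  bn <- bottleneck_scores(g, mode = mode)
  k <- if (is.null(k_bottlenecks)) length(h$hubs) else k_bottlenecks
  b <- identify_bottlenecks(bn, k, degrees = deg)
  cs <- intersect_controllers(h, b, n_nodes = igraph::vcount(g))
  cs$bn_scores <- bn
  cs$degrees <- deg
  cs
}
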