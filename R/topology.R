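#' Per-node degree profile
#'
#' In-, out- and total degree of every node of the directed simple
#' network. Total degree (the connectivity used by the hub rule and the
#' attack experiment) is the sum of in- and out-degree, so the grand
#' total over nodes equals twice the link count.
#'
#' @param net a `signaling_network` or igraph.
#' @return data.frame with columns `node`, `gamma_in`, `gamma_out`,
#'   `gamma` (one row per node, in vertex order).
#' @export
degree_profile <- function(net) {
  g <- as_graph(net)
  if (igraph::vcount(g) == 0) stop("empty network")
  data.frame(
    node = igraph::V(g)$name,
    gamma_in = igraph::degree(g, mode = "in"),
    gamma_out = igraph::degree(g, mode = "out"),
    gamma = igraph::degree(g, mode = "all"),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Local clustering coefficients and their network mean
#'
#' Computed on the undirected simple projection: for a node with k >= 2
#' neighbors the coefficient is the fraction of neighbor pairs that are
#' themselves linked; nodes with fewer than two neighbors score 0 and are
#' included in the network mean.
#'
#' @param net a `signaling_network` or igraph.
#' @return list with `per_node` (named numeric vector) and `mean`.
#' @export
clustering_coefficient <- function(net) {
  u <- undirected_projection(net)
  if (igraph::vcount(u) == 0) stop("empty network")
  cc <- igraph::transitivity(u, type = "local", isolates = "zero")
  names(cc) <- igraph::V(u)$name
  list(per_node = cc, mean = mean(cc))
}

#' Characteristic path length
#'
#' Mean shortest-path length over all ordered pairs of distinct nodes
#' that are connected in the chosen metric space (undirected projection
#' by default); unreachable pairs are excluded.
#'
#' @param net a `signaling_network` or igraph.
#' @param directed_distances use directed shortest paths instead of the
#'   undirected projection.
#' @return mean shortest-path length (>= 1 when any edge exists).
#' @export
characteristic_path_length <- function(net, directed_distances = FALSE) {
  g <- if (directed_distances) as_graph(net) else undirected_projection(net)
  d <- igraph::distances(g, mode = "out")
  diag(d) <- Inf
  finite <- d[is.finite(d)]
  if (length(finite) == 0) stop("no connected pair of nodes")
  mean(finite)
}

#' Mean number of distinct neighbors
#'
#' A neighbor is an adjacent node in the undirected projection, counted
#' once even if linked in both directions.
#'
#' @param net a `signaling_network` or igraph.
#' @return mean neighbor count over all nodes.
#' @export
avg_neighbors <- function(net) {
  u <- undirected_projection(net)
  if (igraph::vcount(u) == 0) stop("empty network")
  mean(igraph::degree(u))
}

#' Number of weakly connected components
#'
#' @param net a `signaling_network` or igraph.
#' @return component count of the undirected projection.
#' @export
count_components <- function(net) {
  g <- as_graph(net)
  if (igraph::vcount(g) == 0) stop("empty network")
  igraph::components(g, mode = "weak")$no
}

#' Fit a power law to a degree distribution
#'
#' Ordinary least squares on the log-log degree-frequency table, the
#' convention of Cytoscape's Network Analyzer: build the frequency table
#' degree -> node count, drop degree 0, and regress log10(count) on
#' log10(degree). The slope is the exponent Gamma; R is the Pearson
#' correlation of the fit and R^2 its square. A flat frequency table
#' (zero variance in the counts) yields slope 0 with R^2 reported as 0.
#'
#' @param degrees vector of non-negative integer degrees (one per node).
#' @return a `powerlaw_fit`: list with `gamma`, `r`, `r2`, `n_points`.
#' @export
powerlaw_fit <- function(degrees) {
  degrees <- degrees[degrees > 0]
  tab <- table(degrees)
  k <- as.numeric(names(tab))
  cnt <- as.numeric(tab)
  if (length(k) < 3) stop("insufficient support for fit: need >= 3 distinct positive degrees")
  x <- log10(k)
  y <- log10(cnt)
  if (stats::sd(y) == 0) {
    fit <- list(gamma = 0, r = 0, r2 = 0, n_points = length(k))
  } else {
    beta <- stats::coef(stats::lm(y ~ x))
    r <- stats::cor(x, y)
    fit <- list(gamma = unname(beta[2]), r = r, r2 = r^2, n_points = length(k))
  }
  structure(fit, class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("Power-law fit (log-log OLS): Gamma = %.3f, R = %.3f, R^2 = %.3f (%d degree values)\n",
              x$gamma, x$r, x$r2, x$n_points))
  invisible(x)
}

#' Summarize network topology
#'
#' Assembles the standard topological parameters of a curated signaling
#' network: node/link counts, weak components, mean local clustering,
#' characteristic path length, mean neighbor count, and power-law fits
#' of the in- and out-degree distributions.
#'
#' @param net a `signaling_network` or igraph.
#' @param directed_distances use directed distances for the path length.
#' @param allow_degenerate if `TRUE`, a shattered network (no connected
#'   pair) or an unfittable degree distribution yields `NA` entries
#'   instead of an error — used while tracking attack trajectories.
#' @return a `topology_summary`: list with `n_nodes`, `n_links`,
#'   `n_components`, `clustering_coefficient`, `char_path_length`,
#'   `avg_neighbors`, `in_fit`, `out_fit`.
#' @export
topology_summary <- function(net, directed_distances = FALSE,
                             allow_degenerate = FALSE) {
  g <- as_graph(net)
  if (igraph::vcount(g) == 0) stop("empty network")
  soften <- function(expr) {
    if (!allow_degenerate) return(expr())
    tryCatch(expr(), error = function(e) NA)
  }
  # degree fits are reported as NA whenever the distribution has too few
  # distinct values to support one (e.g. a regular graph)
  soft_fit <- function(d) tryCatch(powerlaw_fit(d), error = function(e) NA)
  deg <- degree_profile(g)
  structure(list(
    n_nodes = igraph::vcount(g),
    n_links = igraph::ecount(g),
    n_components = count_components(g),
    clustering_coefficient = clustering_coefficient(g)$mean,
    char_path_length = soften(function()
      characteristic_path_length(g, directed_distances)),
    avg_neighbors = avg_neighbors(g),
    in_fit = soft_fit(deg$gamma_in),
    out_fit = soft_fit(deg$gamma_out)
  ), class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  fmt <- function(v) if (length(v) == 1 && is.na(v)) "NA" else sprintf("%.3f", v)
  cat("Network topology\n")
  cat("  Number of nodes:               ", x$n_nodes, "\n")
  cat("  Number of links:               ", x$n_links, "\n")
  cat("  Number of connected components:", x$n_components, "\n")
  cat("  Clustering coefficient:        ", fmt(x$clustering_coefficient), "\n")
  cat("  Char. path length:             ", fmt(x$char_path_length), "\n")
  cat("  Avg. number of neighbors:      ", fmt(x$avg_neighbors), "\n")
  for (side in c("in_fit", "out_fit")) {
    f <- x[[side]]
    lab <- if (side == "in_fit") "In degree " else "Out degree"
    if (inherits(f, "powerlaw_fit")) {
      cat(sprintf("  %s: Gamma = %.3f, R = %.3f, R^2 = %.3f\n",
                  lab, f$gamma, f$r, f$r2))
    } else {
      cat("  ", lab, ": fit unavailable\n", sep = "")
    }
  }
  invisible(x)
}

# Flatten a topology_summary to a single-row data frame (for trajectories
# and machine-readable reports).
summary_row <- function(s) {
  gf <- function(f, what) if (inherits(f, "powerlaw_fit")) f[[what]] else NA_real_
  data.frame(
    n_nodes = s$n_nodes, n_links = s$n_links, n_components = s$n_components,
    clustering_coefficient = s$clustering_coefficient,
    char_path_length = if (is.na(s$char_path_length[1])) NA_real_ else s$char_path_length,
    avg_neighbors = s$avg_neighbors,
    in_gamma = gf(s$in_fit, "gamma"), in_r2 = gf(s$in_fit, "r2"),
    out_gamma = gf(s$out_fit, "gamma"), out_r2 = gf(s$out_fit, "r2")
  )
}
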