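# Brute-force oracles, written without igraph on purpose: they check the
# package's graph metrics through an independent route (dense matrices,
# explicit path enumeration, explicit tree materialization).

# A tiny graph fixture: named nodes, an edge matrix (2 columns of names),
# plus the igraph the implementation consumes.
make_graph <- function(nodes, edges, directed = TRUE) {
  g <- igraph::make_empty_graph(0, directed = directed)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(edges)) g <- igraph::add_edges(g, t(edges))
  list(nodes = nodes, edges = edges, graph = g)
}

# Random simple graph on n nodes with shuffled letter names (to exercise
# lexicographic tie-breaks); optionally resampled until connected.
random_graph <- function(n, p = 0.4, connected = TRUE, directed = FALSE) {
  nodes <- sample(paste0(sample(letters, n), sprintf("%02d", seq_len(n))))
  repeat {
    pairs <- t(combn(n, 2))
    keep <- stats::runif(nrow(pairs)) < p
    edges <- pairs[keep, , drop = FALSE]
    if (directed) {
      flip <- stats::runif(nrow(edges)) < 0.5
      edges[flip, ] <- edges[flip, 2:1]
    }
    A <- matrix(0L, n, n)
    if (nrow(edges)) {
      A[edges] <- 1L
      A[edges[, 2:1, drop = FALSE]] <- 1L
    }
    if (!connected || n == 1 || all(oracle_distances(A) < Inf)) break
  }
  em <- cbind(nodes[edges[, 1]], nodes[edges[, 2]])
  c(make_graph(nodes, em, directed = directed), list(adj = A))
}

# Floyd-Warshall all-pairs shortest distances on a 0/1 adjacency matrix.
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    Dk <- outer(D[, k], D[k, ], `+`)
    D <- pmin(D, Dk)
  }
  D
}

# Number of shortest paths between every pair, by dynamic programming
# over distance layers from each source.
oracle_path_counts <- function(A, D) {
  n <- nrow(A)
  S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    S[s, s] <- 1
    reach <- which(is.finite(D[s, ]) & D[s, ] > 0)
    for (v in reach[order(D[s, reach])]) {
      preds <- which(A[, v] > 0 & D[s, ] == D[s, v] - 1)
      S[s, v] <- sum(S[s, preds])
    }
  }
  S
}

# Exact closeness: 1 / mean distance to reachable nodes, 0 if none.
oracle_closeness <- function(A) {
  D <- oracle_distances(A)
  diag(D) <- Inf
  apply(D, 1, function(row) {
    r <- row[is.finite(row)]
    if (length(r) == 0) 0 else 1 / mean(r)
  })
}

# Exact normalized betweenness over unordered pairs, component-wise
# normalization (N-1)(N-2)/2.
oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  S <- oracle_path_counts(A, D)
  comp_sizes <- rowSums(is.finite(D))
  b <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(D[s, t])) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t]) {
        acc <- acc + S[s, v] * S[v, t] / S[s, t]
      }
    }
    N <- comp_sizes[v]
    b[v] <- if (N > 2) acc / ((N - 1) * (N - 2) / 2) else 0
  }
  b
}

# Bottleneck-score oracle: for each root, materialize the shortest-path
# tree under the declared parent rule (lexicographically smallest
# neighbor one layer closer), then walk every tree path from the root
# explicitly and count, per vertex, how many paths meet it.
oracle_bn <- function(A, nodes, directed = FALSE, count_endpoint = TRUE) {
  n <- nrow(A)
  lex <- order(nodes)          # lex[i] = index of i-th smallest name
  lexrank <- match(seq_len(n), lex)
  Ad <- A                      # A already oriented if directed
  D <- if (directed) {
    # directed distances: Floyd-Warshall on the directed adjacency
    Dm <- matrix(Inf, n, n); Dm[Ad > 0] <- 1; diag(Dm) <- 0
    for (k in seq_len(n)) Dm <- pmin(Dm, outer(Dm[, k], Dm[k, ], `+`))
    Dm
  } else oracle_distances(A)
  bn <- integer(n)
  for (s in seq_len(n)) {
    reach <- which(is.finite(D[s, ]))
    nt <- length(reach)
    if (nt < 2) next
    father <- rep(NA_integer_, n)
    for (v in setdiff(reach, s)) {
      preds <- which(Ad[, v] > 0 & D[s, ] == D[s, v] - 1)
      father[v] <- preds[which.min(lexrank[preds])]
    }
    cnt <- integer(n)
    for (w in setdiff(reach, s)) {
      v <- w
      while (v != s) {                 # the path s -> w, walked upward
        cnt[v] <- cnt[v] + 1L
        v <- father[v]
      }
      if (!count_endpoint) cnt[w] <- cnt[w] - 1L
    }
    hit <- setdiff(reach, s)[cnt[setdiff(reach, s)] > nt / 4]
    bn[hit] <- bn[hit] + 1L
  }
  bn
}

# Local clustering by explicit triangle counting on the adjacency matrix.
oracle_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(A[nb, nb, drop = FALSE]) / 2
    2 * links / (k * (k - 1))
  }, numeric(1))
}

# Characteristic path length from the Floyd-Warshall distances.
oracle_cpl <- function(A) {
  D <- oracle_distances(A)
  diag(D) <- Inf
  mean(D[is.finite(D)])
}

oracle_n_components <- function(A) {
  D <- oracle_distances(A)
  memb <- integer(nrow(A))
  cid <- 0L
  for (v in seq_len(nrow(A))) {
    if (memb[v] == 0L) {
      cid <- cid + 1L
      memb[is.finite(D[v, ])] <- cid
    }
  }
  cid
}

# Degrees as a directed signaling network ingests them.
adj_to_net <- function(fix) {
  signaling_network(fix$graph)
}
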