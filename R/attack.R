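# Network topology transition under attack: iterative targeted removal
# of the most connected nodes versus removal of the same number of
# random nodes, with collapse detection after each cycle. Scale-free
# networks are expected to survive the random attack and shatter under
# the targeted one.

.attack_run <- function(net, pick_fun, cycles, mode, fraction = NA_real_,
                        seed = NA_integer_) {
  g <- as_graph(net)
  n0 <- igraph::vcount(g)
  if (n0 == 0) stop("empty network")
  trajectory <- list(topology_summary(g, allow_degenerate = TRUE))
  removed <- vector("list", cycles)
  giant_fraction <- numeric(cycles)
  for (cy in seq_len(cycles)) {
    victims <- pick_fun(g, cy)
    if (length(victims) == 0) stop("attack removes zero nodes")
    removed[[cy]] <- victims
    g <- igraph::delete_vertices(g, victims)
    trajectory[[cy + 1]] <- topology_summary(g, allow_degenerate = TRUE)
    giant_fraction[cy] <-
      max(igraph::components(g, mode = "weak")$csize) / n0
  }
  col <- detect_collapse(trajectory[[1]], trajectory[[cycles + 1]],
                         giant_fraction[cycles])
  structure(list(
    mode = mode, fraction_per_cycle = fraction, cycles = cycles,
    removed = removed, trajectory = trajectory,
    giant_fraction = giant_fraction,
    collapsed = col$collapsed, reasons = col$reasons, seed = seed
  ), class = "attack_result")
}

#' Targeted attack: iterative removal of the most connected nodes
#'
#' Each cycle removes the `ceiling(fraction * current_n)` nodes of
#' highest total degree (ties broken by higher bottleneck score, then
#' lexicographic name) and re-examines the topology. The defaults —
#' 2.5% per cycle over two cycles — reproduce the hub-removal
#' experiment; the removed count is 2.5% of the surviving nodes, the
#' only reading under which two cycles remove enough hubs to threaten a
#' ~641-node network.
#'
#' @param net a `signaling_network` or igraph.
#' @param fraction proportion of surviving nodes removed per cycle,
#'   in (0, 1).
#' @param cycles number of attack cycles (>= 1).
#' @return an `attack_result`: removal lists per cycle, a trajectory of
#'   [topology_summary()] objects (before + after each cycle), the giant
#'   weak-component fraction relative to the original node count, and
#'   the collapse verdict with its reasons.
#' @export
targeted_attack <- function(net, fraction = 0.025, cycles = 2) {
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  if (cycles < 1) stop("cycles must be >= 1")
  pick <- function(g, cy) {
    n <- igraph::vcount(g)
    k <- ceiling(fraction * n)
    if (k < 1 || n == 0) return(character(0))
    deg <- igraph::degree(g, mode = "all")
    bn <- bottleneck_scores(g)
    nm <- igraph::V(g)$name
    nm[order(-deg, -bn[nm], nm)][seq_len(k)]
  }
  .attack_run(net, pick, cycles, mode = "targeted", fraction = fraction)
}

#' Random attack: removal of uniformly chosen nodes
#'
#' The control arm: each cycle removes `n_per_cycle` nodes sampled
#' uniformly without replacement among the survivors. With the same
#' per-cycle removal counts as a targeted run it measures how much of
#' the damage is due to targeting hubs rather than to losing nodes.
#'
#' @param net a `signaling_network` or igraph.
#' @param n_per_cycle nodes removed per cycle (a single count, recycled,
#'   or one count per cycle, e.g. the `lengths(removed)` of a targeted
#'   run); must be >= 1.
#' @param cycles number of cycles.
#' @param seed mandatory RNG seed; identical seeds give identical runs.
#' @return an `attack_result`.
#' @export
random_attack <- function(net, n_per_cycle, cycles = 2, seed) {
  if (missing(seed)) stop("seed is mandatory for a random attack")
  if (cycles < 1) stop("cycles must be >= 1")
  n_per_cycle <- rep_len(n_per_cycle, cycles)
  if (any(n_per_cycle < 1)) stop("attack removes zero nodes")
  set.seed(seed)
  pick <- function(g, cy) {
    k <- n_per_cycle[cy]
    nm <- igraph::V(g)$name
    if (k > length(nm)) stop("cannot remove ", k, " of ", length(nm), " nodes")
    sample(nm, k)
  }
  .attack_run(net, pick, cycles, mode = "random", seed = seed)
}

#' Detect topological collapse after an attack
#'
#' A network is judged collapsed when its giant weak component has
#' fallen below `giant_threshold` of the original node count, or when
#' the total-degree distribution no longer supports a power law (log-log
#' fit R^2 below `r2_threshold`, or too few distinct degrees to fit) —
#' i.e. the scale-free topology itself has been destroyed. Both
#' thresholds are declared definitions, exposed as arguments.
#'
#' @param before,after `topology_summary` objects.
#' @param giant_fraction giant-component fraction after the attack.
#' @param giant_threshold collapse cutoff on the giant fraction (0.5).
#' @param r2_threshold collapse cutoff on the degree-fit R^2 (0.5).
#' @return list with `collapsed` (logical) and `reasons` (character).
#' @export
detect_collapse <- function(before, after, giant_fraction,
                            giant_threshold = 0.5, r2_threshold = 0.5) {
  stopifnot(inherits(before, "topology_summary"),
            inherits(after, "topology_summary"))
  reasons <- character(0)
  if (giant_fraction < giant_threshold) {
    reasons <- c(reasons, sprintf("giant component fraction %.3f < %.2f",
                                  giant_fraction, giant_threshold))
  }
  deg_fit_r2 <- function(s) {
    f_in <- s$in_fit; f_out <- s$out_fit
    if (!inherits(f_in, "powerlaw_fit") && !inherits(f_out, "powerlaw_fit")) {
      return(NA_real_)
    }
    max(if (inherits(f_in, "powerlaw_fit")) f_in$r2 else -Inf,
        if (inherits(f_out, "powerlaw_fit")) f_out$r2 else -Inf)
  }
  r2 <- deg_fit_r2(after)
  r2_before <- deg_fit_r2(before)
  if (is.na(r2)) {
    # only evidence of collapse if the distribution was fittable before
    if (!is.na(r2_before)) {
      reasons <- c(reasons, "degree distribution no longer fittable")
    }
  } else if (r2 < r2_threshold) {
    reasons <- c(reasons, sprintf("degree power-law fit R^2 %.3f < %.2f",
                                  r2, r2_threshold))
  }
  list(collapsed = length(reasons) > 0, reasons = reasons)
}

#' @export
print.attack_result <- function(x, ...) {
  cat(sprintf("%s attack, %d cycle(s)", x$mode, x$cycles))
  if (!is.na(x$fraction_per_cycle)) {
    cat(sprintf(", %.1f%% of nodes per cycle", 100 * x$fraction_per_cycle))
  }
  cat("\n")
  for (cy in seq_len(x$cycles)) {
    cat(sprintf("  cycle %d: removed %d node(s); giant fraction %.3f\n",
                cy, length(x$removed[[cy]]), x$giant_fraction[cy]))
  }
  cat("  collapsed:", x$collapsed)
  if (length(x$reasons)) cat(" (", paste(x$reasons, collapse = "; "), ")", sep = "")
  cat("\n")
  invisible(x)
}
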