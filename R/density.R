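# Kernel density estimation in 1D and 2D with mode-based subpopulation
# detection: used to ask whether the network's controllers split into
# distinct groups (e.g. hub.BN in the degree x BN-score plane) and which
# of them sit isolated in low-density regions.

# Silverman's rule per dimension: h = 0.9 min(sd, IQR/1.34) n^(-1/(d+4)),
# floored at 1e-6 of the data range (or 1e-6 absolute for degenerate
# dimensions) so zero-variance inputs still yield a proper density.
.silverman_bw <- function(x, d, n) {
  s <- stats::sd(x)
  iqr <- stats::IQR(x) / 1.34
  spread <- if (is.na(s)) 0 else min(s, if (iqr > 0) iqr else Inf)
  h <- 0.9 * spread * n^(-1 / (d + 4))
  rng <- diff(range(x))
  floor_h <- max(1e-6 * rng, 1e-6)
  max(h, floor_h)
}

.as_point_matrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 1)
  points <- as.matrix(points)
  if (!all(is.finite(points))) stop("coordinates must be finite")
  if (nrow(points) < 1) stop("need at least one point")
  if (!ncol(points) %in% c(1, 2)) stop("only 1D and 2D supported")
  points
}

#' Gaussian kernel density estimate on a regular grid
#'
#' Product Gaussian kernel with a per-dimension bandwidth (Silverman's
#' rule by default); per-dimension bandwidths make the estimate adapt to
#' each axis' scale, so axes with incommensurate units (e.g. node degree
#' versus BN score) are weighted equivalently to z-standardized
#' coordinates while the grid stays on the original scale. The grid
#' spans the data range plus 3 bandwidths on each side.
#'
#' @param points numeric vector (1D) or two-column matrix (2D).
#' @param bandwidth optional per-dimension bandwidth(s); recycled.
#' @param grid_size grid points per axis (>= 128 by default).
#' @return a `kde_result`: list with `dims`, `points`, `bandwidth`,
#'   `grid` (list of `axes` and `spacing`), `density` (vector or
#'   matrix, integrates to ~1 over the grid), and empty `subpopulations`
#'   / `isolated` slots to be filled by [find_subpopulations()].
#' @export
kde_estimate <- function(points, bandwidth = NULL, grid_size = 128) {
  pts <- .as_point_matrix(points)
  n <- nrow(pts)
  d <- ncol(pts)
  if (is.null(bandwidth)) {
    bandwidth <- vapply(seq_len(d), function(j) .silverman_bw(pts[, j], d, n),
                        numeric(1))
  } else {
    bandwidth <- rep_len(as.numeric(bandwidth), d)
    if (any(bandwidth <= 0)) stop("bandwidth must be positive")
  }
  axes <- lapply(seq_len(d), function(j) {
    lo <- min(pts[, j]) - 3 * bandwidth[j]
    hi <- max(pts[, j]) + 3 * bandwidth[j]
    seq(lo, hi, length.out = grid_size)
  })
  spacing <- vapply(axes, function(a) a[2] - a[1], numeric(1))
  K <- lapply(seq_len(d), function(j)
    outer(axes[[j]], pts[, j],
          function(g, p) stats::dnorm(g - p, sd = bandwidth[j])))
  density <- if (d == 1) {
    rowMeans(K[[1]])
  } else {
    (K[[1]] %*% t(K[[2]])) / n   # [x-grid, y-grid]
  }
  structure(list(dims = d, points = pts, bandwidth = bandwidth,
                 grid = list(axes = axes, spacing = spacing),
                 density = density,
                 subpopulations = NULL, isolated = NULL),
            class = "kde_result")
}

# Exact KDE evaluated at arbitrary locations (same kernel/bandwidth).
.kde_at <- function(kde, at) {
  at <- .as_point_matrix(at)
  pts <- kde$points
  n <- nrow(pts)
  dens <- rep(0, nrow(at))
  for (j in seq_len(kde$dims)) {
    Kj <- outer(at[, j], pts[, j],
                function(g, p) stats::dnorm(g - p, sd = kde$bandwidth[j]))
    dens <- if (j == 1) Kj else dens * Kj
  }
  rowMeans(dens) * n / n  # mean over points of the product kernel
}

# Neighbor offsets on the grid (2 in 1D, 8 in 2D), fixed order so that
# plateau tie-breaks are deterministic.
.grid_neighbors <- function(d) {
  if (d == 1) return(matrix(c(-1L, 1L), ncol = 1))
  as.matrix(expand.grid(dx = -1:1, dy = -1:1)[-5, , drop = FALSE])
}

#' Detect subpopulations and isolated points in a density estimate
#'
#' Subpopulations are the basins of attraction of the density surface's
#' significant modes. Grid cells are swept in order of decreasing
#' density; each cell joins the basin of its steepest-ascent neighbor,
#' so basins are exactly the regions from which discrete gradient ascent
#' reaches each mode. Two adjacent basins stay distinct only when the
#' saddle between them is prominent — the density at the meeting cell
#' must fall below `merge_ratio` times the lower of the two peak heights
#' — which prevents sampling noise on one cluster from splitting it.
#' The low-density level is `density_quantile` (default 5%) of the peak
#' density: modes below it are discarded and every point whose own local
#' density falls below it is flagged isolated. Each input point ends up
#' in exactly one subpopulation (the basin of its nearest grid cell) or
#' in the isolated set.
#'
#' @param kde a `kde_result` from [kde_estimate()].
#' @param density_quantile fraction (default 0.05) of the peak density
#'   below which a region counts as low-density / isolated.
#' @param merge_ratio two modes are kept separate only if their saddle
#'   dips below this fraction (default 0.5) of the lower peak.
#' @param min_members a subpopulation is a group: a basin holding fewer
#'   than this many points (default 2) is reclassified as isolated
#'   point(s), matching the convention that a lone detached point is an
#'   outlier, not a population.
#' @return the `kde_result` with `subpopulations` (list of lists:
#'   `mode` location, `members` point indices) and `isolated` (integer
#'   point indices) filled in, plus `level` (the density cutoff).
#' @export
find_subpopulations <- function(kde, density_quantile = 0.05,
                                merge_ratio = 0.5, min_members = 2) {
  stopifnot(inherits(kde, "kde_result"))
  pts <- kde$points
  n <- nrow(pts)
  d <- kde$dims
  point_dens <- .kde_at(kde, pts)
  level <- density_quantile * max(kde$density)
  isolated <- which(point_dens < level)

  axes <- kde$grid$axes
  dens <- if (d == 1) matrix(kde$density, ncol = 1) else kde$density
  nr <- nrow(dens); nc <- ncol(dens)
  ncell <- nr * nc

  # flat neighbor index table (NA outside the grid), fixed offset order
  nb <- .grid_neighbors(d)
  if (d == 1) nb <- cbind(nb, 0L)
  ri <- rep(seq_len(nr), times = nc)
  ci <- rep(seq_len(nc), each = nr)
  neigh <- vapply(seq_len(nrow(nb)), function(k) {
    rr <- ri + nb[k, 1]; cc <- ci + nb[k, 2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    ifelse(ok, (cc - 1L) * nr + rr, NA_integer_)
  }, integer(ncell))

  # union-find over basins
  parent <- integer(0)
  peak_height <- numeric(0)
  peak_cell <- integer(0)
  find_root <- function(b) {
    while (parent[b] != b) b <- parent[b]
    b
  }

  basin <- integer(ncell)          # 0 = unassigned
  dvec <- as.vector(dens)
  ord <- order(-dvec)
  for (cell in ord) {
    nbs <- neigh[cell, ]
    nbs <- nbs[!is.na(nbs)]
    ab <- basin[nbs]
    ab <- ab[ab > 0L]
    if (!length(ab)) {             # local max: a new basin
      parent <- c(parent, length(parent) + 1L)
      peak_height <- c(peak_height, dvec[cell])
      peak_cell <- c(peak_cell, cell)
      basin[cell] <- length(parent)
      next
    }
    roots <- unique(vapply(ab, find_root, integer(1)))
    # steepest-ascent assignment: basin of the highest neighbor
    best <- nbs[which.max(dvec[nbs])]
    basin[cell] <- find_root(basin[best])
    if (length(roots) > 1) {
      # this cell is a saddle between basins; merge non-prominent pairs
      keep <- roots[order(-peak_height[roots])]
      main <- keep[1]
      for (b in keep[-1]) {
        if (dvec[cell] >= merge_ratio * peak_height[b]) {
          parent[b] <- main
        }
      }
    }
  }

  surviving <- which(parent == seq_along(parent) & peak_height >= level)
  surviving <- surviving[order(-peak_height[surviving])]

  nearest_cell <- function(p) {
    ij <- vapply(seq_len(d), function(j) which.min(abs(axes[[j]] - p[j])), 1L)
    if (d == 1) ij <- c(ij, 1L)
    (ij[2] - 1L) * nr + ij[1]
  }
  member_root <- integer(n)
  active <- setdiff(seq_len(n), isolated)
  for (i in active) {
    member_root[i] <- find_root(basin[nearest_cell(pts[i, ])])
  }
  # a point whose basin peak fell below the level joins the nearest
  # surviving mode (can only happen to borderline non-isolated points)
  if (length(surviving)) {
    stray <- active[!(member_root[active] %in% surviving)]
    for (i in stray) {
      locs <- t(vapply(surviving, function(b) {
        cl <- peak_cell[b]
        c(axes[[1]][(cl - 1L) %% nr + 1L],
          if (d == 2) axes[[2]][(cl - 1L) %/% nr + 1L] else 0)
      }, numeric(2)))
      dist2 <- rowSums((locs[, seq_len(d), drop = FALSE] -
                          matrix(pts[i, ], nrow(locs), d, byrow = TRUE))^2)
      member_root[i] <- surviving[which.min(dist2)]
    }
  }

  subpop <- lapply(surviving, function(b) {
    cl <- peak_cell[b]
    loc <- c(axes[[1]][(cl - 1L) %% nr + 1L],
             if (d == 2) axes[[2]][(cl - 1L) %/% nr + 1L])
    members <- which(member_root == b)
    list(mode = loc, members = members)
  })
  subpop <- Filter(function(sp) length(sp$members) > 0, subpop)
  # a basin holding fewer points than min_members is not a population:
  # its points are detached stragglers and join the isolated set
  tiny <- vapply(subpop, function(sp) length(sp$members) < min_members,
                 logical(1))
  if (any(tiny) && !all(tiny)) {
    isolated <- sort(c(isolated, unlist(lapply(subpop[tiny], `[[`, "members"))))
    subpop <- subpop[!tiny]
  }

  kde$subpopulations <- subpop
  kde$isolated <- isolated
  kde$level <- level
  kde$point_density <- point_dens
  kde
}

#' @export
print.kde_result <- function(x, ...) {
  cat(sprintf("%dD Gaussian KDE of %d points (bandwidth %s)\n",
              x$dims, nrow(x$points),
              paste(sprintf("%.4g", x$bandwidth), collapse = " x ")))
  if (!is.null(x$subpopulations)) {
    cat(sprintf("  %d subpopulation(s), %d isolated point(s)\n",
                length(x$subpopulations), length(x$isolated)))
    for (i in seq_along(x$subpopulations)) {
      sp <- x$subpopulations[[i]]
      cat(sprintf("    subpopulation %d: %d member(s), mode at (%s)\n",
                  i, length(sp$members),
                  paste(sprintf("%.3g", sp$mode), collapse = ", ")))
    }
  }
  invisible(x)
}
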