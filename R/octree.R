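# Dynamic unbalanced octree grouping (DUOS): capacity-constrained octree
# construction, proportional per-leaf quota allocation with largest-remainder
# rounding, and density-filtered representative selection. An FPS baseline
# and fixed-size ball grouping round out the sampling layer.

#' Build a capacity-constrained (unbalanced) octree
#'
#' Recursive midpoint subdivision of the cloud's bounding cube: a cell is
#' split into its eight octants whenever it holds more than `leaf_capacity`
#' points and has not reached `max_depth`. Dense regions therefore produce
#' deeper leaves than sparse regions -- the octree adapts to the density
#' heterogeneity typical of livestock scans (dense trunk, sparse limbs).
#'
#' @param cloud a `point_cloud`.
#' @param leaf_capacity maximum points per leaf (>= 1), except that a leaf
#'   at `max_depth` may exceed it (guards against duplicate points).
#' @param max_depth maximum subdivision depth (>= 1).
#' @return root `octree_node`: a nested list with `lo`, `hi` (cell corners),
#'   `depth`, and either `children` (list of up to 8 nodes, empty octants
#'   dropped) or `idx` (1-based point indices, leaves only).
#' @export
build_unbalanced_octree <- function(cloud, leaf_capacity = 64L,
                                    max_depth = 10L) {
  stopifnot(leaf_capacity >= 1, max_depth >= 1)
  p <- cloud$points
  if (nrow(p) == 0L) stop("cannot build an octree on an empty cloud")
  lo <- apply(p, 2L, min)
  hi <- apply(p, 2L, max)
  side <- max(hi - lo, .Machine$double.eps)
  centre <- (lo + hi) / 2
  lo <- centre - side / 2
  hi <- centre + side / 2
  root <- octree_split(p, seq_len(nrow(p)), lo, hi, 0L,
                       as.integer(leaf_capacity), as.integer(max_depth))
  class(root) <- "octree_node"
  root
}

octree_split <- function(p, idx, lo, hi, depth, capacity, max_depth) {
  if (length(idx) <= capacity || depth >= max_depth)
    return(list(lo = lo, hi = hi, depth = depth, idx = idx))
  mid <- (lo + hi) / 2
  oct <- 1L +
    (p[idx, 1L] >= mid[1L]) +
    2L * (p[idx, 2L] >= mid[2L]) +
    4L * (p[idx, 3L] >= mid[3L])
  children <- vector("list", 8L)
  for (o in 1:8) {
    sub <- idx[oct == o]
    if (length(sub) == 0L) next
    b <- c((o - 1L) %% 2L, (o - 1L) %/% 2L %% 2L, (o - 1L) %/% 4L)
    clo <- ifelse(b == 1L, mid, lo)
    chi <- ifelse(b == 1L, hi, mid)
    children[[o]] <- octree_split(p, sub, clo, chi, depth + 1L,
                                  capacity, max_depth)
  }
  list(lo = lo, hi = hi, depth = depth,
       children = children[!vapply(children, is.null, logical(1L))])
}

#' Collect the leaves of an octree
#' @param node root (or any) `octree_node`.
#' @return list of leaf nodes in depth-first octant order.
#' @export
octree_leaves <- function(node) {
  if (is.null(node$children)) return(list(node))
  do.call(c, lapply(node$children, octree_leaves))
}

#' Representative point of a leaf cell
#'
#' The leaf's point nearest to the geometric centre of the leaf cell; ties
#' broken by lowest point index.
#'
#' @param cloud the `point_cloud` the octree was built on.
#' @param leaf a leaf `octree_node`.
#' @return 1-based index of the representative point.
#' @export
leaf_representative <- function(cloud, leaf) {
  if (!is.null(leaf$children)) stop("leaf_representative needs a leaf node")
  if (length(leaf$idx) == 0L) stop("empty leaf")
  ranked_leaf_candidates(cloud, leaf)[1L]
}

# leaf point indices ranked by distance to the cell centre (ties: lower index)
ranked_leaf_candidates <- function(cloud, leaf) {
  centre <- (leaf$lo + leaf$hi) / 2
  d <- sweep(cloud$points[leaf$idx, , drop = FALSE], 2L, centre)
  leaf$idx[order(rowSums(d * d), leaf$idx)]
}

#' Proportional quota allocation across leaves
#'
#' Splits `n1` sampling slots across leaves proportionally to leaf size,
#' using largest-remainder rounding (remainder ties broken by larger leaf,
#' then lower leaf order). Quotas are capped at leaf sizes; any excess is
#' redistributed one slot at a time to the leaf with the largest remaining
#' capacity.
#'
#' @param leaf_sizes positive integer vector of points per leaf.
#' @param n1 total number of slots; must not exceed `sum(leaf_sizes)`.
#' @return integer vector of quotas, summing to `n1`, each `<=` leaf size.
#' @export
allocate_quota <- function(leaf_sizes, n1) {
  leaf_sizes <- as.integer(leaf_sizes)
  stopifnot(all(leaf_sizes >= 1L))
  total <- sum(leaf_sizes)
  if (n1 > total) stop("n1 exceeds total point count across leaves")
  exact <- n1 * leaf_sizes / total
  q <- floor(exact)
  need <- n1 - sum(q)
  if (need > 0L) {
    ord <- order(-(exact - q), -leaf_sizes, seq_along(leaf_sizes))
    take <- ord[seq_len(need)]
    q[take] <- q[take] + 1
  }
  over <- sum(pmax(q - leaf_sizes, 0))
  q <- pmin(q, leaf_sizes)
  while (over > 0L) {
    cap <- leaf_sizes - q
    i <- which.max(cap)
    q[i] <- q[i] + 1L
    over <- over - 1L
  }
  as.integer(q)
}

#' DUOS sampling: density-filtered octree representative selection
#'
#' Builds a capacity-constrained octree, allocates per-leaf quotas
#' proportional to leaf population, and fills each quota with the leaf's
#' points ranked by distance to the leaf-cell centre, skipping candidates
#' whose local density (neighbours within `density_radius`) falls below
#' `density_threshold` -- these are treated as noise and recorded in
#' `rejected_low_density`. Leaf deficits are redistributed to the leaves
#' with the most remaining eligible candidates; if the whole cloud runs out
#' of eligible candidates the density test is relaxed (threshold 0) for the
#' remaining deficit, so exactly `n1` unique centres are always returned.
#'
#' @param cloud a `point_cloud`.
#' @param n1 number of sampling centres (`<=` point count).
#' @param leaf_capacity,max_depth octree parameters, see
#'   [build_unbalanced_octree()].
#' @param density_radius density ball radius in the cloud's units.
#' @param density_threshold minimum neighbour count for a centre.
#' @param density_scope `"cloud"` measures density against the whole cloud
#'   (default); `"leaf"` only within the candidate's own leaf.
#' @return a `duos_sampling` list: `center_indices` (length `n1`, unique),
#'   `per_leaf_quota` (selected count per leaf, sums to `n1`),
#'   `rejected_low_density` (indices skipped by the density test),
#'   `relaxed` (TRUE if the threshold had to be relaxed), `densities`.
#' @export
duos_sample <- function(cloud, n1, leaf_capacity = 64L, max_depth = 10L,
                        density_radius = 2.5, density_threshold = 3L,
                        density_scope = c("cloud", "leaf")) {
  density_scope <- match.arg(density_scope)
  n <- n_points(cloud)
  if (n1 > n) stop("n1 exceeds the number of points")
  if (n1 == 0L)
    return(structure(list(center_indices = integer(0L),
                          per_leaf_quota = integer(0L),
                          rejected_low_density = integer(0L),
                          relaxed = FALSE), class = "duos_sampling"))
  tree <- build_unbalanced_octree(cloud, leaf_capacity, max_depth)
  leaves <- octree_leaves(tree)
  sizes <- vapply(leaves, function(l) length(l$idx), integer(1L))
  quota <- allocate_quota(sizes, n1)

  if (density_scope == "cloud") {
    dens <- cloud_densities(cloud, density_radius)
  } else {
    dens <- integer(n)
    for (l in leaves) {
      sub <- cloud$points[l$idx, , drop = FALSE]
      dens[l$idx] <- cpp_radius_counts(sub, density_radius)
    }
  }

  ranked <- lapply(leaves, function(l) ranked_leaf_candidates(cloud, l))
  eligible <- lapply(ranked, function(r) r[dens[r] >= density_threshold])
  rejected <- unlist(lapply(ranked, function(r)
    r[dens[r] < density_threshold]), use.names = FALSE)

  selected <- vector("list", length(leaves))
  taken <- integer(length(leaves))
  for (i in seq_along(leaves)) {
    k <- min(quota[i], length(eligible[[i]]))
    selected[[i]] <- eligible[[i]][seq_len(k)]
    taken[i] <- k
  }
  deficit <- n1 - sum(taken)
  # redistribute to leaves that still have eligible candidates,
  # most remaining first (ties: leaf order)
  while (deficit > 0L) {
    remaining <- vapply(eligible, length, integer(1L)) - taken
    i <- which.max(remaining)
    if (remaining[i] <= 0L) break
    taken[i] <- taken[i] + 1L
    selected[[i]] <- eligible[[i]][seq_len(taken[i])]
    deficit <- deficit - 1L
  }
  relaxed <- FALSE
  if (deficit > 0L) {
    # every remaining point fails the density test: relax it for the deficit
    relaxed <- TRUE
    chosen <- unlist(selected, use.names = FALSE)
    for (i in seq_along(leaves)) {
      if (deficit == 0L) break
      extra <- setdiff(ranked[[i]], chosen)
      k <- min(deficit, length(extra))
      if (k > 0L) {
        selected[[i]] <- c(selected[[i]], extra[seq_len(k)])
        taken[i] <- taken[i] + k
        chosen <- c(chosen, extra[seq_len(k)])
        deficit <- deficit - k
      }
    }
  }
  centres <- unlist(selected, use.names = FALSE)
  structure(list(center_indices = centres,
                 per_leaf_quota = taken,
                 rejected_low_density =
                   setdiff(as.integer(rejected), centres),
                 relaxed = relaxed,
                 densities = dens),
            class = "duos_sampling")
}

#' Farthest point sampling baseline
#'
#' Standard iterative FPS: starting from a seeded random index, repeatedly
#' selects the point farthest from the already-selected set.
#'
#' @param cloud a `point_cloud`.
#' @param n1 number of samples (`<=` point count).
#' @param seed integer seed choosing the start index.
#' @return integer vector of `n1` unique 1-based indices.
#' @export
fps_sample <- function(cloud, n1, seed = 1L) {
  n <- n_points(cloud)
  if (n1 > n) stop("n1 exceeds the number of points")
  if (n1 == 0L) return(integer(0L))
  set.seed(as.integer(seed))
  start <- sample.int(n, 1L)
  cpp_fps(cloud$points, as.integer(n1), start)
}

#' Fixed-size ball grouping around sampling centres
#'
#' For each centre, up to `max_group_size` points within `radius`
#' (nearest-first); underfull groups are padded by repeating the centre so
#' every group has the same size (the fixed-size contract the network
#' expects). Group coordinates are re-expressed relative to the centre.
#'
#' @param cloud a `point_cloud`.
#' @param center_indices 1-based centre indices.
#' @param radius grouping ball radius (> 0).
#' @param max_group_size group size K.
#' @return list with `indices` (centres x K matrix of point indices,
#'   nearest-first, centre-padded), `counts` (points actually within the
#'   ball, capped at K) and `rel` (centres x K x 3 array of centred
#'   coordinates; padded slots are zero).
#' @export
group_neighbors <- function(cloud, center_indices, radius, max_group_size) {
  stopifnot(radius > 0, max_group_size >= 1)
  centres <- as.integer(center_indices)
  idx <- cpp_ball_group(cloud$points, centres, radius,
                        as.integer(max_group_size))
  nc <- length(centres)
  K <- max_group_size
  pts <- cloud$points
  flat <- pts[as.vector(idx), , drop = FALSE] -
    pts[rep(centres, times = K), , drop = FALSE]
  counts <- integer(nc)
  for (i in seq_len(nc)) {
    within <- idx[i, ] != centres[i]
    # the centre itself is always a true member; padded slots repeat it
    counts[i] <- min(K, sum(within) + 1L)
  }
  list(indices = idx, counts = counts,
       rel = array(flat, dim = c(nc, K, 3L)))
}
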