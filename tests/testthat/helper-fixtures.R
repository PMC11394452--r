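# shared fixtures and independent oracles

seeded_cloud <- function(n, seed, spread = 50) {
  set.seed(seed)
  point_cloud(matrix(runif(3 * n, -spread, spread), ncol = 3))
}

# O(N^2) neighbour counts, the contractual reference for the spatial index
brute_density <- function(points, radius) {
  d <- as.matrix(dist(points))
  rowSums(d <= radius) - 1L
}

# direct-formula IDW, independent of the package implementation
naive_idw <- function(known_points, known_features, query_points, k, p) {
  out <- matrix(0, nrow(query_points), ncol(known_features))
  k <- min(k, nrow(known_points))
  for (q in seq_len(nrow(query_points))) {
    d <- sqrt(colSums((t(known_points) - query_points[q, ])^2))
    nn <- order(d)[seq_len(k)]
    if (d[nn[1L]] == 0) {
      out[q, ] <- known_features[nn[1L], ]
    } else {
      w <- 1 / d[nn]^p
      out[q, ] <- colSums(known_features[nn, , drop = FALSE] * w) / sum(w)
    }
  }
  out
}

# recursive octree walk collecting (leaf size, depth, indices)
walk_octree <- function(node) {
  if (is.null(node$children))
    return(list(list(size = length(node$idx), depth = node$depth,
                     idx = node$idx)))
  do.call(c, lapply(node$children, walk_octree))
}

# points sampled on a circle / ellipse in 2D
circle_points <- function(n, r = 1, arc = c(0, 2 * pi), jitter = 0) {
  th <- seq(arc[1L], arc[2L], length.out = n)
  cbind(r * cos(th), r * sin(th)) +
    matrix(rnorm(2 * n, sd = jitter), n, 2)
}

ellipse_points <- function(n, a, b, arc = c(0, 2 * pi)) {
  th <- seq(arc[1L], arc[2L], length.out = n)
  cbind(a * cos(th), b * sin(th))
}

# small default cow, cached across test files (same session)
.cow_cache <- new.env(parent = emptyenv())
test_cow <- function(seed = 1, points_body = 8000, noise_sd = 0, ...) {
  key <- paste(seed, points_body, noise_sd, ...)
  if (is.null(.cow_cache[[key]]))
    .cow_cache[[key]] <- generate_cow(cow_spec(seed = seed,
                                               points_body = points_body,
                                               noise_sd = noise_sd, ...))
  .cow_cache[[key]]
}

cow_part <- function(cow, labels) {
  subset_cloud(cow$cloud, cow$cloud$labels %in% labels)
}
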