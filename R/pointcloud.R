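#' @useDynLib bovimetry, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats quantile kmeans runif rnorm median cov var
#' @importFrom utils head read.table write.table write.csv
NULL

# Coordinate convention used throughout: right-handed frame, units cm,
# x = anteroposterior axis (head -> tail increasing), y = mediolateral,
# z = vertical (up); the ground is a plane z = constant.

#' Construct a point cloud
#'
#' A point cloud is a matrix of 3D coordinates in centimetres, optionally
#' carrying a fixed-width per-point feature matrix. Coordinates follow the
#' package frame convention: x anteroposterior (head to tail), y mediolateral,
#' z vertical (up).
#'
#' @param points numeric matrix (or coercible) with 3 columns x, y, z in cm.
#' @param features optional numeric matrix with one row per point.
#' @return an object of class `point_cloud`.
#' @export
point_cloud <- function(points, features = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must have 3 columns (x, y, z)")
  storage.mode(points) <- "double"
  if (!all(is.finite(points))) stop("all coordinates must be finite")
  colnames(points) <- c("x", "y", "z")
  if (!is.null(features)) {
    features <- as.matrix(features)
    storage.mode(features) <- "double"
    if (nrow(features) != nrow(points))
      stop("features must have one row per point")
    if (!all(is.finite(features))) stop("all features must be finite")
  }
  structure(list(points = points, features = features),
            class = "point_cloud")
}

#' Attach part labels to a point cloud
#'
#' Part labels follow the seven-part cattle scheme: the four legs are
#' labelled 0-3 and the body is split into front (4), middle (5) and
#' back (6).
#'
#' @param cloud a `point_cloud`.
#' @param labels integer vector in `0:6`, one per point.
#' @return an object of class `labeled_point_cloud` (also a `point_cloud`).
#' @export
labeled_point_cloud <- function(cloud, labels) {
  if (!inherits(cloud, "point_cloud")) cloud <- point_cloud(cloud)
  labels <- as.integer(labels)
  if (length(labels) != n_points(cloud))
    stop("labels length must equal point count")
  if (anyNA(labels) || any(labels < 0L | labels > 6L))
    stop("labels must be integers in 0..6")
  cloud$labels <- labels
  class(cloud) <- c("labeled_point_cloud", "point_cloud")
  cloud
}

#' Number of points in a cloud
#' @param cloud a `point_cloud`.
#' @return integer point count.
#' @export
n_points <- function(cloud) nrow(cloud$points)

#' Subset a point cloud by index
#' @param cloud a `point_cloud` or `labeled_point_cloud`.
#' @param idx integer or logical index of points to keep.
#' @return cloud of the same class restricted to `idx`, order preserved.
#' @export
subset_cloud <- function(cloud, idx) {
  out <- cloud
  out$points <- cloud$points[idx, , drop = FALSE]
  if (!is.null(cloud$features))
    out$features <- cloud$features[idx, , drop = FALSE]
  if (!is.null(cloud$labels)) out$labels <- cloud$labels[idx]
  out
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<%s: %d points%s%s>\n",
              class(x)[1L], n_points(x),
              if (is.null(x$features)) "" else
                sprintf(", %d features", ncol(x$features)),
              if (is.null(x$labels)) "" else
                sprintf(", labels %s", paste(sort(unique(x$labels)),
                                             collapse = "/"))))
  invisible(x)
}

#' Centre a cloud and scale it to the unit ball
#'
#' Translates the cloud so its centroid is at the origin and divides by the
#' maximum Euclidean norm, so every point lies in \[-1, 1\]^3 and the
#' farthest point has norm exactly 1. The centroid and scale are returned so
#' the transform can be inverted with [denormalize_cloud()].
#'
#' @param cloud a `point_cloud`.
#' @return list with `cloud` (normalized), `centroid` (length-3) and
#'   `scale` (max norm, cm).
#' @export
normalize_cloud <- function(cloud) {
  p <- cloud$points
  if (nrow(p) == 0L) stop("cannot normalize an empty cloud")
  centroid <- colMeans(p)
  p <- sweep(p, 2L, centroid)
  scale <- sqrt(max(rowSums(p * p)))
  if (scale == 0) stop("degenerate cloud: all points identical (scale 0)")
  out <- cloud
  out$points <- p / scale
  list(cloud = out, centroid = centroid, scale = scale)
}

#' Invert [normalize_cloud()]
#' @param cloud a normalized `point_cloud`.
#' @param centroid,scale as returned by [normalize_cloud()].
#' @return cloud in the original frame.
#' @export
denormalize_cloud <- function(cloud, centroid, scale) {
  out <- cloud
  out$points <- sweep(cloud$points * scale, 2L, centroid, `+`)
  out
}

#' Radius outlier filter
#'
#' Retains exactly the points that have at least `min_neighbors` other
#' points within Euclidean distance `radius`; survivor order is preserved.
#'
#' @param cloud a `point_cloud` (labels/features filtered alongside).
#' @param radius neighbourhood radius in cm (> 0).
#' @param min_neighbors minimum neighbour count (>= 0) to keep a point.
#' @return the filtered cloud.
#' @export
radius_filter <- function(cloud, radius, min_neighbors) {
  stopifnot(radius > 0, min_neighbors >= 0)
  if (n_points(cloud) == 0L) return(cloud)
  if (min_neighbors == 0) return(cloud)
  counts <- cpp_radius_counts(cloud$points, radius)
  subset_cloud(cloud, counts >= min_neighbors)
}

#' Local point density
#'
#' Number of *other* points within `radius` of the query point (the query
#' point itself is excluded, so an isolated point has density 0).
#'
#' @param cloud a `point_cloud`.
#' @param query_index 1-based point index.
#' @param radius ball radius in cm (> 0).
#' @return integer neighbour count.
#' @export
density_at <- function(cloud, query_index, radius) {
  stopifnot(radius > 0)
  n <- n_points(cloud)
  if (length(query_index) != 1L || is.na(query_index) ||
      query_index < 1L || query_index > n)
    stop("query_index out of range")
  cpp_radius_counts_query(cloud$points,
                          cloud$points[query_index, , drop = FALSE],
                          as.integer(query_index), radius)[1L]
}

# densities of every point against the whole cloud (self-excluded)
cloud_densities <- function(cloud, radius) {
  cpp_radius_counts(cloud$points, radius)
}

#' Rigid augmentation
#'
#' Applies a seeded random rigid transform -- rotation about the vertical
#' axis by an angle in `angle_range` and translation drawn from
#' `translate_sd` -- leaving labels untouched and pairwise distances intact.
#'
#' @param cloud a `labeled_point_cloud` (or plain `point_cloud`).
#' @param seed integer seed.
#' @param angle_range rotation range in radians (default full turn).
#' @param translate_sd isotropic translation standard deviation in cm.
#' @return the transformed cloud, same class.
#' @export
augment_cloud <- function(cloud, seed, angle_range = c(0, 2 * pi),
                          translate_sd = 10) {
  set.seed(as.integer(seed))
  theta <- runif(1L, angle_range[1L], angle_range[2L])
  shift <- rnorm(3L, sd = translate_sd)
  rotate_z(cloud, theta, shift)
}

#' Rotate a cloud about the z axis and translate
#' @param cloud a `point_cloud`.
#' @param theta rotation angle in radians (counter-clockwise seen from +z).
#' @param shift length-3 translation in cm.
#' @return the transformed cloud.
#' @export
rotate_z <- function(cloud, theta, shift = c(0, 0, 0)) {
  R <- matrix(c(cos(theta), sin(theta), 0,
                -sin(theta), cos(theta), 0,
                0, 0, 1), 3L, 3L)
  out <- cloud
  out$points <- sweep(cloud$points %*% t(R), 2L, shift, `+`)
  colnames(out$points) <- c("x", "y", "z")
  out
}
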