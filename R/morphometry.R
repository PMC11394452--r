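# Segmented-part body-size measurement: heights by leg-midpoint slicing,
# circumferences by transverse slicing + 2D alpha-shape contours (with
# symmetry repair of one-sided occlusion), body length by two-pass density
# keypoint extraction + K-means end clustering.
#
# Transverse slices live in (u, v) = (y, z) slice coordinates; the cannon
# slice is horizontal, (u, v) = (x, y).

#' 2D contour
#' @param points n x 2 matrix of (u, v) coordinates in cm, ordered by angle
#'   about their centroid.
#' @param closed whether the contour closes back on its first point.
#' @return a `contour2d` object.
#' @export
contour2d <- function(points, closed = TRUE) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L)
  structure(list(points = points, closed = closed), class = "contour2d")
}

#' Hoof-level ground reference
#'
#' Robust ground height: the 2nd percentile (configurable) of z over all leg
#' points, which rejects stray below-ground outliers.
#'
#' @param legs a `point_cloud` of leg points (labels 0-3 pooled), or a
#'   `labeled_point_cloud` from which labels 0-3 are taken.
#' @param prob quantile used (default 0.02).
#' @return ground height z0 in cm.
#' @export
ground_reference <- function(legs, prob = 0.02) {
  if (!is.null(legs$labels)) legs <- subset_cloud(legs, legs$labels <= 3L)
  if (n_points(legs) == 0L) stop("no leg points: cannot locate the ground")
  unname(quantile(legs$points[, 3L], prob))
}

#' Top-of-leg keypoint
#'
#' Centroid of the top `q` percent of a leg's points by height; used as the
#' per-leg anchor that positions the height and thoracic slicing planes.
#'
#' @param leg a `point_cloud` of one leg.
#' @param q percentage of points (by z, from the top) averaged; `q = 100`
#'   gives the leg centroid.
#' @return named length-3 keypoint (x, y, z).
#' @export
leg_top_keypoint <- function(leg, q = 5) {
  if (n_points(leg) == 0L) stop("empty leg cloud")
  z <- leg$points[, 3L]
  thr <- quantile(z, 1 - q / 100)
  top <- leg$points[z >= thr, , drop = FALSE]
  kp <- colMeans(top)
  names(kp) <- c("x", "y", "z")
  kp
}

#' Transverse slice of a cloud
#'
#' Points with `|x - x_plane| <= thickness/2`, projected to the (y, z)
#' slice plane.
#'
#' @param cloud a `point_cloud`.
#' @param x_plane slicing plane position along the anteroposterior axis, cm.
#' @param thickness slab thickness in cm.
#' @return m x 2 matrix of (u, v) = (y, z) coordinates (possibly 0 rows).
#' @export
slice_transverse <- function(cloud, x_plane, thickness) {
  keep <- abs(cloud$points[, 1L] - x_plane) <= thickness / 2
  cloud$points[keep, c(2L, 3L), drop = FALSE]
}

#' Height measurement (withers or hip)
#'
#' The two leg-top keypoints p0, p1 are midpointed to place the transverse
#' slicing plane; the maximum-z point of the body slice is the height
#' keypoint, and the height is its z minus the ground reference. Using the
#' leg midpoint makes the plane placement robust to a nonstandard stance.
#'
#' @param body a `point_cloud` of the relevant body part (front body for
#'   withers height, back body for hip height).
#' @param left_leg,right_leg `point_cloud`s of the corresponding leg pair.
#' @param z0 ground reference from [ground_reference()].
#' @param thickness slice thickness in cm.
#' @param q leg keypoint quantile, see [leg_top_keypoint()].
#' @return list with `height` (cm), `keypoint` (3D) and `slice_size`.
#' @export
measure_height <- function(body, left_leg, right_leg, z0, thickness = 3,
                           q = 5) {
  p0 <- leg_top_keypoint(left_leg, q)
  p1 <- leg_top_keypoint(right_leg, q)
  pc <- (p0 + p1) / 2
  sl <- slice_transverse(body, pc[["x"]], thickness)
  if (nrow(sl) == 0L) stop("slice empty")
  i <- which.max(sl[, 2L])
  keep <- abs(body$points[, 1L] - pc[["x"]]) <= thickness / 2
  kp <- body$points[keep, , drop = FALSE][i, ]
  names(kp) <- c("x", "y", "z")
  list(height = unname(kp[["z"]] - z0), keypoint = kp,
       slice_size = nrow(sl))
}

## ---- alpha-shape contours --------------------------------------------------

# boundary edges of the 2D alpha shape: an edge (i, j) with |ij| <= 2*alpha
# is on the boundary iff one of the two radius-alpha disks through i and j
# contains no other point strictly inside
alpha_shape_boundary <- function(P, alpha) {
  n <- nrow(P)
  P3 <- cbind(P, 0)
  # candidate neighbours within 2*alpha via the 3D grid (z = 0)
  grp <- cpp_ball_group(P3, seq_len(n), 2 * alpha, n)
  boundary <- logical(n)
  a2 <- alpha^2 * (1 - 1e-9)
  for (i in seq_len(n)) {
    nbr <- unique(grp[i, ])
    nbr <- nbr[nbr > i]  # each pair once
    for (j in nbr) {
      dx <- P[j, 1L] - P[i, 1L]
      dy <- P[j, 2L] - P[i, 2L]
      d2 <- dx * dx + dy * dy
      if (d2 > 4 * alpha^2 || d2 == 0) next
      h <- sqrt(max(alpha^2 - d2 / 4, 0))
      mx <- (P[i, 1L] + P[j, 1L]) / 2
      my <- (P[i, 2L] + P[j, 2L]) / 2
      ux <- -dy / sqrt(d2)
      uy <- dx / sqrt(d2)
      cand <- union(unique(grp[i, ]), unique(grp[j, ]))
      cand <- cand[cand != i & cand != j]
      for (s in c(1, -1)) {
        cx <- mx + s * h * ux
        cy <- my + s * h * uy
        if (length(cand) == 0L ||
            all((P[cand, 1L] - cx)^2 + (P[cand, 2L] - cy)^2 >= a2)) {
          boundary[i] <- TRUE
          boundary[j] <- TRUE
          break
        }
      }
    }
  }
  which(boundary)
}

#' Alpha-shape contour extraction
#'
#' Boundary points of the 2D alpha shape of a slice point set, ordered by
#' angle about their centroid. For convex, densely sampled slices the
#' contour contains the convex hull vertices.
#'
#' @param slice_points m x 2 matrix of slice coordinates.
#' @param alpha alpha-shape disk radius in cm; larger values approach the
#'   convex hull.
#' @return a `contour2d`.
#' @export
extract_contour <- function(slice_points, alpha = 5) {
  P <- as.matrix(slice_points)
  if (nrow(P) < 3L) stop("need at least 3 points to extract a contour")
  idx <- alpha_shape_boundary(P, alpha)
  if (length(idx) < 3L)
    stop("alpha shape found no closed boundary; increase alpha")
  B <- P[idx, , drop = FALSE]
  ctr <- colMeans(B)
  ang <- atan2(B[, 2L] - ctr[2L], B[, 1L] - ctr[1L])
  B <- B[order(ang), , drop = FALSE]
  dup <- c(FALSE, rowSums((B[-1L, , drop = FALSE] -
                             B[-nrow(B), , drop = FALSE])^2) < 1e-18)
  contour2d(B[!dup, , drop = FALSE])
}

#' Closed polygon perimeter of a contour
#'
#' Sum of consecutive point distances plus the closing edge back to the
#' first point.
#'
#' @param contour a `contour2d`, or an ordered n x 2 matrix.
#' @return perimeter in cm.
#' @export
perimeter <- function(contour) {
  P <- if (inherits(contour, "contour2d")) contour$points else
    as.matrix(contour)
  n <- nrow(P)
  if (n < 2L) stop("perimeter needs at least 2 ordered points")
  Q <- rbind(P[-1L, , drop = FALSE], P[1L, , drop = FALSE])
  sum(sqrt(rowSums((Q - P)^2)))
}

# closed polygon length with the chord-to-arc correction (pi/m)/sin(pi/m):
# an m-vertex polygon inscribed in a smooth convex contour understates the
# arc length by that factor, noticeably so for sparse cannon slices
arc_corrected_perimeter <- function(contour) {
  m <- nrow(contour$points)
  perimeter(contour) * (pi / m) / sin(pi / m)
}

# angular bin-averaging + circular moving average of the radius: suppresses
# the chord-length inflation that radial sensor noise causes in a raw
# point-to-point polygon, without shrinking the shape (angles are kept)
smooth_contour <- function(contour, n_bins = NULL, window = 3L) {
  P <- contour$points
  n <- nrow(P)
  if (is.null(n_bins)) n_bins <- max(12L, min(72L, floor(n / 2.5)))
  ctr <- colMeans(P)
  ang <- atan2(P[, 2L] - ctr[2L], P[, 1L] - ctr[1L])
  r <- sqrt(rowSums(sweep(P, 2L, ctr)^2))
  bin <- pmin(floor((ang + pi) / (2 * pi) * n_bins) + 1L, n_bins)
  ab <- tapply(ang, bin, mean)
  rb <- tapply(r, bin, mean)
  m <- length(rb)
  if (m < 3L) return(contour)
  if (window > 1L && m > window) {
    rs <- rb
    half <- window %/% 2L
    for (i in seq_len(m)) {
      idx <- ((i - 1L - half):(i - 1L + half)) %% m + 1L
      rs[i] <- mean(rb[idx])
    }
    rb <- rs
  }
  contour2d(cbind(ctr[1L] + rb * cos(ab), ctr[2L] + rb * sin(ab)))
}

#' Detect an occlusion gap in a contour
#'
#' Finds the largest chord between angularly consecutive contour points
#' (including the wrap-around edge); a gap is flagged when that chord
#' exceeds `gap_threshold` times the median consecutive spacing *and* a
#' sizeable fraction of the contour's overall extent (guarding against
#' false alarms from locally uneven sampling).
#'
#' @param contour a `contour2d`.
#' @param gap_threshold multiple of the median spacing above which the
#'   largest chord counts as a gap (`Inf` never detects).
#' @param min_extent_frac minimum gap chord as a fraction of the contour
#'   bounding-box diagonal.
#' @return list with `gap_present`, `alpha` and `beta` (the flanking
#'   points, in contour order across the gap) and `chord` (gap width, cm).
#' @export
detect_gap <- function(contour, gap_threshold = 8, min_extent_frac = 0.15) {
  P <- contour$points
  n <- nrow(P)
  if (n < 3L)
    return(list(gap_present = FALSE, alpha = NULL, beta = NULL, chord = NA))
  Q <- rbind(P[-1L, , drop = FALSE], P[1L, , drop = FALSE])
  d <- sqrt(rowSums((Q - P)^2))
  i <- which.max(d)
  med <- median(d)
  diag_len <- sqrt(sum((apply(P, 2L, max) - apply(P, 2L, min))^2))
  present <- is.finite(gap_threshold) && d[i] > gap_threshold * med &&
    d[i] > min_extent_frac * diag_len
  list(gap_present = present,
       alpha = P[i, ], beta = Q[i, ], chord = d[i])
}

#' Symmetry repair of an occluded contour
#'
#' The intact arc (all contour points; the gap itself holds none) is
#' mirrored across the vertical axis through the contour's topmost point --
#' the dorsal midline in a transverse body slice -- then rigidly translated
#' so its end meets the gap flank `alpha`; the mirrored points falling in
#' the gap's angular range bridge the gap. With no gap the contour is
#' returned unchanged.
#'
#' @param contour a `contour2d`.
#' @param gap result of [detect_gap()].
#' @return the repaired `contour2d`.
#' @export
repair_contour <- function(contour, gap) {
  if (!isTRUE(gap$gap_present)) return(contour)
  A <- contour$points
  u_top <- A[which.max(A[, 2L]), 1L]
  B <- cbind(2 * u_top - A[, 1L], A[, 2L])
  # rigid shift aligning the reconstruction with the alpha flank
  j <- which.min((B[, 1L] - gap$alpha[1L])^2 + (B[, 2L] - gap$alpha[2L])^2)
  B <- sweep(B, 2L, gap$alpha - B[j, ], `+`)
  # keep only the mirrored points that fall inside the gap's angular range
  ctr <- colMeans(A)
  angle_of <- function(p) atan2(p[, 2L] - ctr[2L], p[, 1L] - ctr[1L])
  a_ang <- angle_of(rbind(gap$alpha))
  b_ang <- angle_of(rbind(gap$beta))
  span <- (b_ang - a_ang) %% (2 * pi)
  rel <- (angle_of(B) - a_ang) %% (2 * pi)
  keep <- rel > 1e-9 & rel < span - 1e-9
  out <- rbind(A, B[keep, , drop = FALSE])
  ctr2 <- colMeans(out)
  ord <- order(atan2(out[, 2L] - ctr2[2L], out[, 1L] - ctr2[1L]))
  out <- out[ord, , drop = FALSE]
  dup <- c(FALSE, rowSums((out[-1L, , drop = FALSE] -
                             out[-nrow(out), , drop = FALSE])^2) < 1e-18)
  contour2d(out[!dup, , drop = FALSE])
}

#' Thoracic circumference
#'
#' The front-leg top keypoints p2, p3 place the transverse plane; the
#' front-body slice there is contoured with the alpha shape, smoothed by
#' angular binning, and its closed perimeter returned.
#'
#' @param front_body `point_cloud` of the front body (label 4).
#' @param left_front_leg,right_front_leg front leg `point_cloud`s.
#' @param thickness slice thickness in cm.
#' @param alpha alpha-shape radius in cm.
#' @param q leg keypoint quantile.
#' @return list with `value` (cm), `x_plane` and `slice_size`.
#' @export
measure_thoracic <- function(front_body, left_front_leg, right_front_leg,
                             thickness = 3, alpha = 5, q = 5) {
  p2 <- leg_top_keypoint(left_front_leg, q)
  p3 <- leg_top_keypoint(right_front_leg, q)
  x_plane <- (p2[["x"]] + p3[["x"]]) / 2
  sl <- slice_transverse(front_body, x_plane, thickness)
  if (nrow(sl) == 0L) stop("slice empty")
  ct <- smooth_contour(extract_contour(sl, alpha))
  list(value = arc_corrected_perimeter(ct), x_plane = x_plane, slice_size = nrow(sl))
}

#' Abdominal circumference with occlusion repair
#'
#' The slicing plane passes through the lowest (minimum z) point p4 of the
#' middle body. If the contour shows an occlusion gap (one flank shielded
#' by a fence), it is repaired by dorsal-midline symmetry before the
#' perimeter is taken.
#'
#' @param mid_body `point_cloud` of the middle body (label 5).
#' @param thickness slice thickness in cm.
#' @param alpha alpha-shape radius in cm.
#' @param gap_threshold see [detect_gap()].
#' @return list with `value` (cm), `keypoint` (p4), `repaired` flag and
#'   `slice_size`.
#' @export
measure_abdominal <- function(mid_body, thickness = 3, alpha = 5,
                              gap_threshold = 8) {
  if (n_points(mid_body) == 0L) stop("middle body empty")
  p4 <- mid_body$points[which.min(mid_body$points[, 3L]), ]
  names(p4) <- c("x", "y", "z")
  sl <- slice_transverse(mid_body, p4[["x"]], thickness)
  if (nrow(sl) == 0L) stop("slice empty")
  ct <- extract_contour(sl, alpha)
  gap <- detect_gap(ct, gap_threshold)
  ct <- repair_contour(ct, gap)
  ct <- smooth_contour(ct)
  list(value = arc_corrected_perimeter(ct), keypoint = p4,
       repaired = isTRUE(gap$gap_present), slice_size = nrow(sl))
}

#' Cannon circumference
#'
#' The front leg is cut into horizontal z-bins; among the bins in the lower
#' half of the leg (below the knee) the one with the smallest
#' anteroposterior extent locates the cannon. The measurement slab (the
#' selected bin widened by one bin on each side, for a stable radius
#' estimate) is contoured in the horizontal (x, y) plane. When the scan
#' covered only one side (the points subtend less than a full turn about
#' their centroid, detected as a largest angular gap above `gap_angle`),
#' the missing side is synthesized by mirroring the observed points across
#' the chord between the gap flanks. The perimeter
#' comes from angular bin-mean radii with a chord-to-arc correction and a
#' curvature debias term `(1 - sigma^2 / (2 r^2))` that removes the
#' outward bias sensor noise induces on a small-radius cross-section
#' (sigma is estimated from the within-bin radial spread).
#'
#' @param front_leg `point_cloud` of a front leg.
#' @param bin_height z-bin height in cm (a value exceeding the leg height
#'   degenerates to a single whole-leg slice).
#' @param gap_angle largest tolerated angular gap in degrees before the
#'   cross-section counts as one-sided.
#' @param min_bin_points bins with fewer points are not candidates.
#' @return list with `value` (cm), `z_bin` (centre height) and
#'   `slice_size`.
#' @export
measure_cannon <- function(front_leg, bin_height = 6, gap_angle = 60,
                           min_bin_points = 5L) {
  if (n_points(front_leg) == 0L) stop("empty leg cloud")
  z <- front_leg$points[, 3L]
  zmin <- min(z)
  zmax <- max(z)
  nb <- max(1L, ceiling((zmax - zmin) / bin_height))
  bin <- pmin(floor((z - zmin) / bin_height) + 1L, nb)
  extent <- rep(Inf, nb)
  for (b in seq_len(nb)) {
    sel <- bin == b
    if (sum(sel) < min_bin_points) next
    xs <- front_leg$points[sel, 1L]
    extent[b] <- max(xs) - min(xs)
  }
  # restrict to the lower half (avoids the elbow/knee flare)
  zc <- zmin + (seq_len(nb) - 0.5) * bin_height
  cand <- which(is.finite(extent) &
                  (zc <= zmin + (zmax - zmin) / 2 | nb == 1L))
  if (length(cand) == 0L) cand <- which(is.finite(extent))
  if (length(cand) == 0L) stop("no populated cannon bin")
  b <- cand[which.min(extent[cand])]
  # pool every populated lower-half bin: the region below the knee is close
  # to a cylinder, and a residual taper is removed by linearly detrending
  # the radius against z, evaluated at the narrowest bin
  sel <- bin %in% cand
  P <- front_leg$points[sel, c(1L, 2L), drop = FALSE]
  zv <- z[sel]
  if (nrow(P) < 3L) stop("cannon slab too sparse")
  ctr <- colMeans(P)
  ang <- sort(atan2(P[, 2L] - ctr[2L], P[, 1L] - ctr[1L]))
  gaps <- c(diff(ang), ang[1L] + 2 * pi - ang[length(ang)])
  if (max(gaps) > gap_angle * pi / 180) {
    # one-sided scan: mirror the observed points across the gap chord
    i <- which.max(gaps)
    a_ang <- ang[i]
    b_ang <- if (i < length(ang)) ang[i + 1L] else ang[1L]
    flank <- function(th) {
      pa <- atan2(P[, 2L] - ctr[2L], P[, 1L] - ctr[1L])
      P[which.min(abs(((pa - th + pi) %% (2 * pi)) - pi)), ]
    }
    a <- flank(a_ang)
    dir <- flank(b_ang) - a
    dir <- dir / sqrt(sum(dir^2))
    rel <- sweep(P, 2L, a)
    along <- rel %*% dir
    perp <- rel - along %*% t(dir)
    P <- rbind(P, P - 2 * perp)
    zv <- c(zv, zv)
  }
  list(value = radial_perimeter(P, zv, zc[b]), z_bin = zc[b],
       slice_size = sum(sel))
}

# perimeter of a roughly circular cross-section from all slab points:
# radius linearly detrended against z (evaluated at z_ref), angular
# bin-mean radii about the centroid, circular moving average, chord-to-arc
# correction, and a curvature debias for sensor noise
radial_perimeter <- function(P, zv = NULL, z_ref = NULL) {
  ctr <- colMeans(P)
  ang <- atan2(P[, 2L] - ctr[2L], P[, 1L] - ctr[1L])
  r <- sqrt(rowSums(sweep(P, 2L, ctr)^2))
  if (!is.null(zv) && length(unique(zv)) > 2L) {
    vz <- var(zv)
    if (vz > 1e-12) {
      slope <- cov(zv, r) / vz
      r <- r - slope * (zv - z_ref)
    }
  }
  n_bins <- max(8L, min(36L, floor(nrow(P) / 8)))
  binb <- pmin(floor((ang + pi) / (2 * pi) * n_bins) + 1L, n_bins)
  ab <- tapply(ang, binb, mean)
  rb <- tapply(r, binb, mean)
  sigma2 <- mean((r - rb[as.character(binb)])^2)
  m <- length(rb)
  if (m >= 3L) {
    rs <- rb
    for (i in seq_len(m))
      rs[i] <- mean(rb[(i - 2L):(i) %% m + 1L])
    rb <- rs
  }
  ct <- contour2d(cbind(ctr[1L] + rb * cos(ab), ctr[2L] + rb * sin(ab)))
  rbar <- mean(rb)
  arc_corrected_perimeter(ct) * max(1 - sigma2 / (2 * rbar^2), 0.8)
}

#' Two-pass density keypoint extraction
#'
#' Pass 1 keeps the points whose local density (neighbours within `radius`)
#' is below `threshold1` -- the sparse end and edge regions where body-length
#' keypoints live. Pass 2 removes, within the kept set, points whose
#' density falls below `threshold2` -- isolated noise.
#'
#' @param cloud a `point_cloud`.
#' @param radius density ball radius in cm.
#' @param threshold1 pass-1 upper density bound (`Inf` keeps everything).
#' @param threshold2 pass-2 lower density bound (0 removes nothing).
#' @return the kept `point_cloud`, with the original indices in
#'   `attr(, "indices")`.
#' @export
density_keypoint_extraction <- function(cloud, radius, threshold1,
                                        threshold2) {
  stopifnot(radius > 0)
  dens <- cloud_densities(cloud, radius)
  keep1 <- which(dens < threshold1)
  kept <- subset_cloud(cloud, keep1)
  if (n_points(kept) > 0L && threshold2 > 0) {
    dens2 <- cloud_densities(kept, radius)
    keep2 <- dens2 >= threshold2
    kept <- subset_cloud(kept, keep2)
    keep1 <- keep1[keep2]
  }
  attr(kept, "indices") <- keep1
  kept
}

#' Body length
#'
#' Two-pass density extraction over the front and back body isolates the
#' sparse shoulder-end and ischial-end regions; K-means with k = 2
#' (initialized at the x-extremes) splits them into clusters D (smaller
#' mean x) and E; the body length is the distance between p5, the minimum-x
#' point of D, and p6, the maximum-x point of E.
#'
#' @param front_body,back_body `point_cloud`s of labels 4 and 6.
#' @param radius density ball radius in cm.
#' @param thresholds length-2 numeric (pass-1 and pass-2 density bounds);
#'   `NULL` sets pass 1 to the 25% density quantile and pass 2 to 2.
#' @param seed K-means seed (initialization is deterministic; the seed
#'   guards the fallback path).
#' @param p6_rule `"max"` (default) takes p6 as the maximum-x point of E,
#'   `"min"` the minimum-x point.
#' @return list with `value` (cm), `p5`, `p6`, `n_candidates`.
#' @export
measure_body_length <- function(front_body, back_body, radius = 6,
                                thresholds = NULL, seed = 1L,
                                p6_rule = c("max", "min")) {
  p6_rule <- match.arg(p6_rule)
  pts <- rbind(front_body$points, back_body$points)
  if (nrow(pts) < 4L) stop("too few body points for body length")
  cl <- point_cloud(pts)
  if (is.null(thresholds)) {
    dens <- cloud_densities(cl, radius)
    thresholds <- c(unname(quantile(dens, 0.25)) + 1, 2)
  }
  kept <- density_keypoint_extraction(cl, radius, thresholds[1L],
                                      thresholds[2L])
  if (n_points(kept) < 2L) stop("density extraction kept too few points")
  kp <- kept$points
  set.seed(as.integer(seed))
  init <- kp[c(which.min(kp[, 1L]), which.max(kp[, 1L])), , drop = FALSE]
  km <- suppressWarnings(kmeans(kp, centers = init))
  mean_x <- tapply(kp[, 1L], km$cluster, mean)
  d_id <- as.integer(names(which.min(mean_x)))
  D <- kp[km$cluster == d_id, , drop = FALSE]
  E <- kp[km$cluster != d_id, , drop = FALSE]
  p5 <- D[which.min(D[, 1L]), ]
  p6 <- if (p6_rule == "max") E[which.max(E[, 1L]), ] else
    E[which.min(E[, 1L]), ]
  names(p5) <- names(p6) <- c("x", "y", "z")
  list(value = sqrt(sum((p6 - p5)^2)), p5 = p5, p6 = p6,
       n_candidates = n_points(kept))
}

#' Relative measurement error
#'
#' `|measured - manual| / manual * 100`, rounded half-up to two decimals
#' (matching how field comparisons against manual tape measurements are
#' reported).
#'
#' @param manual manual reference value in cm (> 0).
#' @param measured measured value in cm.
#' @return relative error in percent.
#' @export
relative_error <- function(manual, measured) {
  stopifnot(all(manual > 0))
  re <- abs(measured - manual) / manual * 100
  floor(re * 100 + 0.5) / 100
}

#' Measurement configuration
#'
#' @param thickness transverse slice thickness, cm.
#' @param alpha alpha-shape radius for body slices, cm.
#' @param q leg keypoint quantile (percent).
#' @param gap_threshold occlusion gap threshold, multiples of median
#'   contour spacing.
#' @param gap_angle one-sided cannon scan threshold, degrees.
#' @param bin_height cannon z-bin height, cm.
#' @param bl_radius body-length density ball radius, cm.
#' @param ground_prob ground reference quantile.
#' @param seed seed for the K-means step.
#' @return a `measure_config` list.
#' @export
measure_config <- function(thickness = 3, alpha = 5, q = 5,
                           gap_threshold = 8, gap_angle = 60,
                           bin_height = 6, bl_radius = 6,
                           ground_prob = 0.02, seed = 1L) {
  structure(list(thickness = thickness, alpha = alpha, q = q,
                 gap_threshold = gap_threshold, gap_angle = gap_angle,
                 bin_height = bin_height, bl_radius = bl_radius,
                 ground_prob = ground_prob, seed = as.integer(seed)),
            class = "measure_config")
}

#' All six body-size parameters from a labelled cloud
#'
#' Part convention: legs 0 front-left, 1 front-right, 2 back-left,
#' 3 back-right; body 4 front, 5 middle, 6 back. Each measurement is
#' attempted independently; a failing parameter is recorded (with the
#' violated precondition) without aborting the rest.
#'
#' @param lcloud a `labeled_point_cloud`.
#' @param config a [measure_config()].
#' @return a `measurement_report`: list with `values` (named WH, HH, BL,
#'   TC, AC, CC; NA where failed), `keypoints`, `diagnostics` (per-parameter
#'   failures, repair flag, slice populations) and `config`.
#' @export
measure_all <- function(lcloud, config = measure_config()) {
  stopifnot(inherits(lcloud, "labeled_point_cloud"))
  part <- function(l) subset_cloud(lcloud, lcloud$labels %in% l)
  legs <- lapply(0:3, function(l) part(l))
  front <- part(4L)
  mid <- part(5L)
  back <- part(6L)
  values <- c(WH = NA_real_, HH = NA_real_, BL = NA_real_,
              TC = NA_real_, AC = NA_real_, CC = NA_real_)
  keypoints <- list()
  diagnostics <- list(errors = list(), repaired = FALSE,
                      slice_sizes = list())
  try_measure <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      diagnostics$errors[[name]] <<- conditionMessage(res)
      return(NULL)
    }
    res
  }
  z0 <- try_measure("ground", ground_reference(lcloud, config$ground_prob))
  if (!is.null(z0)) {
    wh <- try_measure("WH", measure_height(front, legs[[1L]], legs[[2L]],
                                           z0, config$thickness, config$q))
    if (!is.null(wh)) {
      values[["WH"]] <- wh$height
      keypoints$p_withers <- wh$keypoint
      diagnostics$slice_sizes$WH <- wh$slice_size
    }
    hh <- try_measure("HH", measure_height(back, legs[[3L]], legs[[4L]],
                                           z0, config$thickness, config$q))
    if (!is.null(hh)) {
      values[["HH"]] <- hh$height
      keypoints$p_hip <- hh$keypoint
      diagnostics$slice_sizes$HH <- hh$slice_size
    }
  }
  tc <- try_measure("TC", measure_thoracic(front, legs[[1L]], legs[[2L]],
                                           config$thickness, config$alpha,
                                           config$q))
  if (!is.null(tc)) {
    values[["TC"]] <- tc$value
    diagnostics$slice_sizes$TC <- tc$slice_size
  }
  ac <- try_measure("AC", measure_abdominal(mid, config$thickness,
                                            config$alpha,
                                            config$gap_threshold))
  if (!is.null(ac)) {
    values[["AC"]] <- ac$value
    keypoints$p4 <- ac$keypoint
    diagnostics$repaired <- ac$repaired
    diagnostics$slice_sizes$AC <- ac$slice_size
  }
  cc <- try_measure("CC", measure_cannon(legs[[1L]], config$bin_height,
                                         config$gap_angle))
  if (!is.null(cc)) {
    values[["CC"]] <- cc$value
    diagnostics$slice_sizes$CC <- cc$slice_size
  }
  bl <- try_measure("BL", measure_body_length(front, back,
                                              config$bl_radius,
                                              seed = config$seed))
  if (!is.null(bl)) {
    values[["BL"]] <- bl$value
    keypoints$p5 <- bl$p5
    keypoints$p6 <- bl$p6
  }
  structure(list(values = values, keypoints = keypoints,
                 diagnostics = diagnostics, config = config),
            class = "measurement_report")
}

#' @export
print.measurement_report <- function(x, ...) {
  cat("Body-size measurement report (cm):\n")
  print(round(x$values, 2))
  if (length(x$diagnostics$errors))
    cat("failed:", paste(names(x$diagnostics$errors), collapse = ", "),
        "\n")
  invisible(x)
}
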