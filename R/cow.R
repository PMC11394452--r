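# Parametric synthetic-cattle point clouds with analytic ground truth.
# The trunk is a superellipsoid whose transverse cross-sections are ellipses
# (closed-form Ramanujan perimeters); the four legs are cylinders with a
# cannon-like profile: constant radius over the lower part, flaring linearly
# toward the trunk. Density heterogeneity (dense trunk, sparse limbs),
# Gaussian sensor noise, posture bending and one-sided fence occlusion
# emulate field scans of standing cattle. The frame follows the package
# convention: x head -> tail, z up, ground at z = 0, units cm.

# trunk x-profile: cross-section scale factor at u = x / a_x
body_profile <- function(u, m = 4) (pmax(1 - abs(u)^m, 0))^(1 / m)

#' Ramanujan approximation to an ellipse perimeter
#' @param a,b semi-axes in cm.
#' @return approximate perimeter in cm.
#' @export
ramanujan_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Synthetic cow specification
#'
#' @param a_x,a_y,a_z trunk semi-axes in cm (half body length, half width,
#'   half depth).
#' @param h_c trunk centre height above the ground, cm.
#' @param shape_exponent superellipsoid exponent along x (boxier trunk for
#'   larger values).
#' @param chest_frac,hip_frac leg attachment positions as fractions of
#'   `a_x` (front legs at `-chest_frac * a_x`, hind legs at
#'   `+hip_frac * a_x`).
#' @param stance_frac lateral leg offset as a fraction of `a_y`.
#' @param r_top,r_min leg radius at the trunk and over the cannon region,
#'   cm (`r_min <= r_top`).
#' @param cannon_frac fraction of the leg (from the ground) with constant
#'   cannon radius before the linear flare begins.
#' @param points_body number of trunk surface points.
#' @param points_leg points per leg (default `points_body / 60`, keeping
#'   the trunk at least 3x denser per unit area than the limbs).
#' @param noise_sd isotropic Gaussian sensor noise, cm.
#' @param bend_angle total horizontal yaw of the body axis from head to
#'   tail, degrees (a C-shaped nonstandard stance).
#' @param occlusion `NULL`, or `list(side = "left"|"right", fraction)` of
#'   trunk points removed beyond a lateral chord.
#' @param seed integer seed.
#' @return a validated `cow_spec` list.
#' @export
cow_spec <- function(a_x = 80, a_y = 31, a_z = 30, h_c = 100,
                     shape_exponent = 4, chest_frac = 0.55,
                     hip_frac = 0.55, stance_frac = 0.5,
                     r_top = 5.5, r_min = 3.2, cannon_frac = 0.6,
                     points_body = 24000L,
                     points_leg = max(60L, round(points_body / 60)),
                     noise_sd = 0, bend_angle = 0, occlusion = NULL,
                     seed = 1L) {
  spec <- list(a_x = a_x, a_y = a_y, a_z = a_z, h_c = h_c,
               shape_exponent = shape_exponent, chest_frac = chest_frac,
               hip_frac = hip_frac, stance_frac = stance_frac,
               r_top = r_top, r_min = r_min, cannon_frac = cannon_frac,
               points_body = as.integer(points_body),
               points_leg = as.integer(points_leg),
               noise_sd = noise_sd, bend_angle = bend_angle,
               occlusion = occlusion, seed = as.integer(seed))
  for (f in c("a_x", "a_y", "a_z", "h_c", "r_top", "r_min"))
    if (spec[[f]] <= 0) stop("cow_spec field must be positive: ", f)
  if (r_min > r_top) stop("cow_spec: r_min must not exceed r_top")
  if (h_c <= a_z) stop("cow_spec: trunk must clear the ground (h_c > a_z)")
  if (!is.null(occlusion)) {
    if (!occlusion$side %in% c("left", "right"))
      stop("cow_spec field occlusion$side must be 'left' or 'right'")
    if (occlusion$fraction < 0 || occlusion$fraction >= 1)
      stop("cow_spec field occlusion$fraction must be in [0, 1)")
  }
  if (spec$noise_sd < 0) stop("cow_spec field noise_sd must be >= 0")
  structure(spec, class = "cow_spec")
}

# leg radius profile: cannon radius up to cannon_frac of the leg, then
# linear flare to r_top at the trunk
leg_radius <- function(z, z_top, spec) {
  zc <- spec$cannon_frac * z_top
  ifelse(z <= zc, spec$r_min,
         spec$r_min + (spec$r_top - spec$r_min) * (z - zc) / (z_top - zc))
}

leg_positions <- function(spec) {
  # labels: 0 front-left, 1 front-right, 2 back-left, 3 back-right
  # (left = negative y)
  x <- c(-1, -1, 1, 1) * c(spec$chest_frac, spec$chest_frac,
                           spec$hip_frac, spec$hip_frac) * spec$a_x
  y <- c(-1, 1, -1, 1) * spec$stance_frac * spec$a_y
  cbind(x = x, y = y)
}

# leg top: where the leg axis meets the trunk's lower surface
leg_top_z <- function(spec, x_leg, y_leg) {
  s <- body_profile(x_leg / spec$a_x, spec$shape_exponent)
  frac <- pmin(abs(y_leg) / (spec$a_y * s), 0.999)
  spec$h_c - spec$a_z * s * sqrt(1 - frac^2)
}

#' Analytic ground-truth body sizes for a cow specification
#'
#' WH/HH are the trunk top height at the front/hind leg plane; BL is the
#' chord between the body ends (equal to `2 * a_x` for an unbent cow); TC
#' and AC are Ramanujan perimeters of the cross-section ellipses at the
#' chest plane and the belly (deepest) plane; CC is the cannon-circle
#' circumference `2 * pi * r_min`.
#'
#' @param spec a [cow_spec()].
#' @return named numeric vector WH, HH, BL, TC, AC, CC in cm.
#' @export
cow_ground_truth <- function(spec) {
  m <- spec$shape_exponent
  s_chest <- body_profile(spec$chest_frac, m)
  s_hip <- body_profile(spec$hip_frac, m)
  bl <- 2 * spec$a_x
  if (spec$bend_angle != 0) {
    psi <- spec$bend_angle * pi / 180
    R <- 2 * spec$a_x / psi
    bl <- 2 * R * sin(spec$a_x / R)
  }
  c(WH = spec$h_c + spec$a_z * s_chest,
    HH = spec$h_c + spec$a_z * s_hip,
    BL = bl,
    TC = ramanujan_perimeter(spec$a_y * s_chest, spec$a_z * s_chest),
    AC = ramanujan_perimeter(spec$a_y, spec$a_z),
    CC = 2 * pi * spec$r_min)
}

# inverse-CDF sampler over a gridded 1D density
sample_inverse_cdf <- function(n, grid, weight) {
  cdf <- cumsum(weight)
  cdf <- cdf / cdf[length(cdf)]
  u <- runif(n)
  grid[findInterval(u, cdf) + 1L]
}

#' Generate a synthetic cow point cloud with ground truth
#'
#' Surface-samples the trunk (approximately uniformly per unit area, so the
#' high-curvature body ends read as low-density regions, as in real scans)
#' and the four legs; labels are assigned by construction (legs 0-3, body
#' thirds 4/5/6 along x). Bending, sensor noise and occlusion follow the
#' spec. Deterministic given `spec$seed`.
#'
#' @param spec a [cow_spec()].
#' @return list with `cloud` (a `labeled_point_cloud`), `truth`
#'   ([cow_ground_truth()]) and `spec`.
#' @export
generate_cow <- function(spec) {
  if (!inherits(spec, "cow_spec")) stop("spec must be a cow_spec")
  set.seed(spec$seed)
  m <- spec$shape_exponent
  # trunk: sample x with density ~ ring circumference * slant factor
  ug <- seq(-1 + 1e-6, 1 - 1e-6, length.out = 4001L)
  s <- body_profile(ug, m)
  ds <- c(diff(s), 0) / c(diff(ug), 1)
  rbar <- (spec$a_y + spec$a_z) / 2
  w <- s * sqrt(1 + (rbar * ds / spec$a_x)^2)
  u <- sample_inverse_cdf(spec$points_body, ug, w)
  su <- body_profile(u, m)
  # ellipse angle, approximately uniform in arc length
  tg <- seq(0, 2 * pi, length.out = 1441L)[-1441L]
  speed <- sqrt((spec$a_y * sin(tg))^2 + (spec$a_z * cos(tg))^2)
  t <- sample_inverse_cdf(spec$points_body, tg, speed)
  body <- cbind(x = u * spec$a_x,
                y = spec$a_y * su * cos(t),
                z = spec$h_c + spec$a_z * su * sin(t))
  body_label <- ifelse(u < -1 / 3, 4L, ifelse(u > 1 / 3, 6L, 5L))

  # legs: z sampled with density ~ radius (uniform surface density)
  lp <- leg_positions(spec)
  legs <- vector("list", 4L)
  for (l in 1:4) {
    z_top <- leg_top_z(spec, lp[l, 1L], lp[l, 2L])
    zg <- seq(0, z_top, length.out = 801L)
    wz <- leg_radius(zg, z_top, spec)
    zl <- sample_inverse_cdf(spec$points_leg, zg, wz)
    rl <- leg_radius(zl, z_top, spec)
    phi <- runif(spec$points_leg, 0, 2 * pi)
    legs[[l]] <- cbind(x = lp[l, 1L] + rl * cos(phi),
                       y = lp[l, 2L] + rl * sin(phi),
                       z = zl)
  }
  pts <- rbind(do.call(rbind, legs), body)
  labels <- c(rep(0:3, each = spec$points_leg), body_label)

  if (spec$bend_angle != 0) {
    psi <- spec$bend_angle * pi / 180
    R <- 2 * spec$a_x / psi
    al <- pts[, 1L] / R
    newx <- R * sin(al) - pts[, 2L] * sin(al)
    newy <- R * (1 - cos(al)) + pts[, 2L] * cos(al)
    pts[, 1L] <- newx
    pts[, 2L] <- newy
  }
  if (spec$noise_sd > 0)
    pts <- pts + matrix(rnorm(length(pts), sd = spec$noise_sd),
                        ncol = 3L)
  cloud <- labeled_point_cloud(point_cloud(pts), labels)
  if (!is.null(spec$occlusion))
    cloud <- apply_occlusion(cloud, spec$occlusion$side,
                             spec$occlusion$fraction)
  list(cloud = cloud, truth = cow_ground_truth(spec), spec = spec)
}

#' One-sided fence occlusion
#'
#' Removes the given fraction of trunk points lying beyond a lateral chord
#' on the stated side (left = negative y); leg points are untouched.
#'
#' @param cloud a `labeled_point_cloud`.
#' @param side `"left"` or `"right"`.
#' @param fraction fraction of body points removed, in `[0, 1)`.
#' @return the occluded cloud.
#' @export
apply_occlusion <- function(cloud, side = c("left", "right"), fraction) {
  side <- match.arg(side)
  if (fraction < 0 || fraction >= 1)
    stop("occlusion fraction must be in [0, 1)")
  if (fraction == 0) return(cloud)
  body <- cloud$labels >= 4L
  y <- cloud$points[, 2L]
  if (side == "left") {
    chord <- quantile(y[body], fraction)
    drop <- body & y < chord
  } else {
    chord <- quantile(y[body], 1 - fraction)
    drop <- body & y > chord
  }
  subset_cloud(cloud, !drop)
}

#' Generate a reproducible herd of synthetic cows
#'
#' Specs are drawn uniformly from `ranges`; stated fractions of the herd
#' get a bent posture and a one-sided occlusion.
#'
#' @param n_cows herd size.
#' @param seed integer seed; the whole herd is reproducible from it.
#' @param ranges named list of `c(min, max)` ranges for `a_x`, `a_y`,
#'   `a_z`, `clearance` (ground to trunk bottom, so `h_c = clearance +
#'   a_z`), `r_min` and `flare` (`r_top = r_min + flare`).
#' @param points_body,points_leg point counts per cow (defaults as in
#'   [cow_spec()]).
#' @param noise_sd sensor noise in cm.
#' @param bent_fraction,occluded_fraction fractions of the herd generated
#'   with a bent posture (12 degree yaw) / 40% left occlusion.
#' @return list of `generate_cow()` results (cloud, truth, spec).
#' @export
generate_dataset <- function(n_cows, seed = 1L,
                             ranges = list(a_x = c(70, 90),
                                           a_y = c(27, 33),
                                           a_z = c(27, 33),
                                           clearance = c(62, 72),
                                           r_min = c(2.8, 3.6),
                                           flare = c(1.8, 2.6)),
                             points_body = 24000L,
                             points_leg = max(60L, round(points_body / 60)),
                             noise_sd = 0, bent_fraction = 0,
                             occluded_fraction = 0) {
  if (n_cows == 0L) return(list())
  set.seed(as.integer(seed))
  draw <- function(r) runif(n_cows, r[1L], r[2L])
  a_x <- draw(ranges$a_x)
  a_y <- draw(ranges$a_y)
  a_z <- draw(ranges$a_z)
  clearance <- draw(ranges$clearance)
  r_min <- draw(ranges$r_min)
  flare <- draw(ranges$flare)
  bent <- runif(n_cows) < bent_fraction
  occl <- runif(n_cows) < occluded_fraction
  seeds <- sample.int(2^30, n_cows)
  lapply(seq_len(n_cows), function(i) {
    spec <- cow_spec(a_x = a_x[i], a_y = a_y[i], a_z = a_z[i],
                     h_c = clearance[i] + a_z[i], r_min = r_min[i],
                     r_top = r_min[i] + flare[i],
                     points_body = points_body, points_leg = points_leg,
                     noise_sd = noise_sd,
                     bend_angle = if (bent[i]) 12 else 0,
                     occlusion = if (occl[i])
                       list(side = "left", fraction = 0.4) else NULL,
                     seed = seeds[i])
    generate_cow(spec)
  })
}
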