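test_that("ground reference is a robust hoof-level estimate", {
  set.seed(71)
  legs <- point_cloud(cbind(runif(400, -2, 2), runif(400, -2, 2),
                            runif(400, 0, 60)))
  expect_lt(abs(ground_reference(legs)), 2)

  # 1% outliers at z = -10 barely move it
  out <- point_cloud(rbind(legs$points, cbind(0, 0, rep(-10, 4))))
  expect_lt(abs(ground_reference(out) - ground_reference(legs)), 1)
  expect_lt(abs(ground_reference(out)), 1.5)

  empty <- point_cloud(matrix(numeric(0), 0, 3))
  expect_error(ground_reference(empty), "leg")
})

test_that("leg top keypoint sits on the axis near the top", {
  seg <- point_cloud(cbind(0, 0, seq(0, 50, length.out = 200)))
  kp <- leg_top_keypoint(seg)
  expect_gt(kp[["z"]], 48)

  set.seed(72)
  phi <- runif(600, 0, 2 * pi)
  cyl <- point_cloud(cbind(10 + 4 * cos(phi), -3 + 4 * sin(phi),
                           runif(600, 0, 60)))
  kp2 <- leg_top_keypoint(cyl)
  expect_lt(abs(kp2[["x"]] - 10), 1)
  expect_lt(abs(kp2[["y"]] + 3), 1)
  expect_gt(kp2[["z"]], 55)

  expect_equal(unname(leg_top_keypoint(cyl, q = 100)),
               unname(colMeans(cyl$points)), tolerance = 1e-12)
})

test_that("transverse slices select the slab and project to (y, z)", {
  cl <- seeded_cloud(300, 73, spread = 20)
  all_pts <- slice_transverse(cl, 0, 1000)
  expect_equal(all_pts, cl$points[, 2:3], ignore_attr = TRUE)
  expect_equal(nrow(slice_transverse(cl, 500, 1)), 0L)

  # axis-aligned ellipsoid sliced at its centre stays inside the
  # central ellipse up to the slab-induced tolerance
  set.seed(74)
  u <- matrix(rnorm(3000), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  ell <- point_cloud(sweep(u, 2, c(40, 20, 10), `*`))
  sl <- slice_transverse(ell, 0, 2)
  expect_gt(nrow(sl), 0)
  expect_true(all((sl[, 1] / 20)^2 + (sl[, 2] / 10)^2 <= 1 + 1e-6))
})

test_that("height measurement slices at the leg midpoint", {
  # box-shaped body with top z = 130 above legs on the ground
  set.seed(75)
  body <- point_cloud(cbind(runif(4000, -40, 40), runif(4000, -20, 20),
                            runif(4000, 60, 130)))
  leg_l <- point_cloud(cbind(runif(300, -22, -18), runif(300, -15, -12),
                             runif(300, 0, 60)))
  leg_r <- point_cloud(cbind(runif(300, -22, -18), runif(300, 12, 15),
                             runif(300, 0, 60)))
  h <- measure_height(body, leg_l, leg_r, z0 = 0)
  expect_equal(h$height, 130, tolerance = 0.01 * 130)
  expect_equal(h$keypoint[["x"]], -20, tolerance = 2)

  # asymmetric stance: keypoint plane stays between the legs
  leg_r2 <- point_cloud(sweep(leg_r$points, 2, c(6, 0, 0), `+`))
  h2 <- measure_height(body, leg_l, leg_r2, z0 = 0)
  expect_equal(h2$height, h$height, tolerance = 0.02 * h$height)

  empty <- point_cloud(matrix(numeric(0), 0, 3))
  expect_error(measure_height(empty, leg_l, leg_r, 0), "slice empty")
})

test_that("alpha-shape contours trace boundaries", {
  circ <- circle_points(40, r = 10)[-40, ]
  ct <- extract_contour(circ, alpha = 3)
  expect_equal(nrow(ct$points), 39L)

  # dense filled disk: contour points near the rim
  set.seed(76)
  rr <- 10 * sqrt(runif(800))
  th <- runif(800, 0, 2 * pi)
  disk <- cbind(rr * cos(th), rr * sin(th))
  ctd <- extract_contour(disk, alpha = 2)
  rad <- sqrt(rowSums(ctd$points^2))
  expect_true(all(rad > 10 - 2 * 2))

  # square lattice: the four corners are on the contour
  lat <- as.matrix(expand.grid(0:10, 0:10))
  ctl <- extract_contour(lat, alpha = 1.5)
  for (corner in list(c(0, 0), c(10, 0), c(0, 10), c(10, 10)))
    expect_true(any(ctl$points[, 1] == corner[1] &
                      ctl$points[, 2] == corner[2]))

  expect_error(extract_contour(circ[1:2, ], 3), "at least 3")
})

test_that("perimeter is the closed polygon length", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_identical(perimeter(sq), 4)
  expect_equal(perimeter(rbind(c(0, 0), c(3, 4))), 10)

  ng <- circle_points(101, r = 1)[-101, ]
  expect_equal(perimeter(ng), 200 * sin(pi / 100), tolerance = 1e-9)

  # invariance under rotation, translation and cyclic re-indexing
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  moved <- sweep(ng %*% t(R), 2, c(5, -3), `+`)
  expect_equal(perimeter(moved), perimeter(ng), tolerance = 1e-9)
  expect_equal(perimeter(ng[c(40:100, 1:39), ]), perimeter(ng),
               tolerance = 1e-9)

  # lower bound: at least twice the diameter of the point set
  set.seed(77)
  poly <- extract_contour(matrix(runif(60, 0, 10), ncol = 2), alpha = 6)
  diam <- max(dist(poly$points))
  expect_gte(perimeter(poly), 2 * diam - 1e-9)
})

test_that("gap detection flags a missing arc with its flanks", {
  full <- contour2d(circle_points(120, r = 20)[-120, ])
  expect_false(detect_gap(full)$gap_present)
  expect_false(detect_gap(full, gap_threshold = Inf)$gap_present)

  # 40% of the arc removed
  part <- contour2d(circle_points(90, r = 20, arc = c(0, 1.2 * pi)))
  g <- detect_gap(part)
  expect_true(g$gap_present)
  ends <- rbind(part$points[1, ], part$points[nrow(part$points), ])
  spacing <- 20 * 1.2 * pi / 90
  expect_lt(min(sqrt(rowSums((ends - rbind(g$alpha, g$alpha))^2))),
            2 * spacing)
  expect_lt(min(sqrt(rowSums((ends - rbind(g$beta, g$beta))^2))),
            2 * spacing)
})

test_that("symmetry repair restores occluded contours", {
  # half circle: repaired perimeter within 2% of the full circle
  half <- contour2d(circle_points(80, r = 15, arc = c(-pi / 2, pi / 2)))
  g <- detect_gap(half)
  expect_true(g$gap_present)
  rep1 <- repair_contour(half, g)
  expect_equal(perimeter(rep1), 2 * pi * 15, tolerance = 0.02 * 2 * pi * 15)

  # ellipse missing one lateral side
  a <- 30; b <- 25
  th <- seq(-0.4 * pi, 0.4 * pi, length.out = 120)
  lat <- contour2d(cbind(a * cos(th), b * sin(th)))
  g2 <- detect_gap(lat)
  expect_true(g2$gap_present)
  rep2 <- repair_contour(lat, g2)
  expect_equal(perimeter(rep2), ramanujan_perimeter(a, b),
               tolerance = 0.02 * ramanujan_perimeter(a, b))

  # occluded fractions up to 45%
  for (frac in c(0.15, 0.30, 0.45)) {
    arc <- c(-pi * (1 - frac), pi * (1 - frac))
    ctf <- contour2d(circle_points(150, r = 12, arc = arc + pi / 2))
    gf <- detect_gap(ctf)
    expect_true(gf$gap_present)
    repf <- repair_contour(ctf, gf)
    expect_equal(perimeter(repf), 2 * pi * 12,
                 tolerance = 0.02 * 2 * pi * 12)
  }

  # no gap: identity
  nog <- detect_gap(full <- contour2d(circle_points(100, 5)[-100, ]))
  expect_identical(repair_contour(full, nog), full)
})

test_that("thoracic circumference matches the analytic cross-section", {
  cow <- test_cow(seed = 81)
  tc <- measure_thoracic(cow_part(cow, 4), cow_part(cow, 0),
                         cow_part(cow, 1))
  expect_equal(tc$value, cow$truth[["TC"]],
               tolerance = 0.03 * cow$truth[["TC"]])

  # circular cross-section: within 2% of 2*pi*r
  set.seed(82)
  n <- 4000
  xc <- runif(n, -50, 50)
  th <- runif(n, 0, 2 * pi)
  tube <- point_cloud(cbind(xc, 25 * cos(th), 100 + 25 * sin(th)))
  legl <- point_cloud(cbind(runif(200, -1, 1), runif(200, -26, -24),
                            runif(200, 0, 75)))
  legr <- point_cloud(cbind(runif(200, -1, 1), runif(200, 24, 26),
                            runif(200, 0, 75)))
  tc2 <- measure_thoracic(tube, legl, legr)
  expect_equal(tc2$value, 2 * pi * 25, tolerance = 0.02 * 2 * pi * 25)

  # legs detached from the body along x: empty slice
  far <- point_cloud(sweep(legl$points, 2, c(500, 0, 0), `+`))
  expect_error(measure_thoracic(tube, far, far), "slice empty")
})

test_that("abdominal circumference survives one-sided occlusion", {
  cow <- test_cow(seed = 83, points_body = 16000)
  ac <- measure_abdominal(cow_part(cow, 5))
  expect_false(ac$repaired)
  expect_equal(ac$value, cow$truth[["AC"]],
               tolerance = 0.03 * cow$truth[["AC"]])

  occ <- apply_occlusion(cow$cloud, "left", 0.4)
  mid <- subset_cloud(occ, occ$labels == 5L)
  ac2 <- measure_abdominal(mid)
  expect_true(ac2$repaired)
  expect_equal(ac2$value, ac$value, tolerance = 0.03 * ac$value)

  empty <- point_cloud(matrix(numeric(0), 0, 3))
  expect_error(measure_abdominal(empty), "empty")
})

test_that("cannon circumference finds the narrowest leg level", {
  # gently tapered leg: minimum radius at the hoof
  set.seed(84)
  n <- 800
  zz <- runif(n, 0, 60)
  rr <- 3 + 0.8 * zz / 60
  ph <- runif(n, 0, 2 * pi)
  leg <- point_cloud(cbind(rr * cos(ph), rr * sin(ph), zz))
  cc <- measure_cannon(leg)
  expect_equal(cc$value, 2 * pi * 3, tolerance = 0.04 * 2 * pi * 3)

  # constant radius: any bin works
  legc <- point_cloud(cbind(4 * cos(ph), 4 * sin(ph), zz))
  cc2 <- measure_cannon(legc)
  expect_equal(cc2$value, 2 * pi * 4, tolerance = 0.04 * 2 * pi * 4)

  # bin taller than the leg degenerates to a single slice
  cc3 <- measure_cannon(legc, bin_height = 1000)
  expect_equal(cc3$value, 2 * pi * 4, tolerance = 0.04 * 2 * pi * 4)

  # one-sided scan: mirrored completion
  half <- ph < pi
  legh <- point_cloud(cbind(4 * cos(ph[half]), 4 * sin(ph[half]),
                            zz[half]))
  cc4 <- measure_cannon(legh)
  expect_equal(cc4$value, 2 * pi * 4, tolerance = 0.06 * 2 * pi * 4)
})

test_that("density keypoint extraction keeps sparse shells, drops noise", {
  set.seed(85)
  n <- 5000
  u <- matrix(rnorm(3 * n), ncol = 3)
  rad <- 10 * runif(n)^(1 / 3)
  ball <- point_cloud(u / sqrt(rowSums(u^2)) * rad)
  interior <- median(sapply(sample(n, 200), function(i)
    density_at(ball, i, 3)))
  kept <- density_keypoint_extraction(ball, 3, interior * 0.6, 0)
  shell <- sqrt(rowSums(kept$points^2))
  expect_gt(n_points(kept), 0)
  expect_true(all(shell > 10 * 0.8))

  # a lone outlier survives pass 1 but is removed by pass 2
  with_out <- point_cloud(rbind(ball$points, c(50, 50, 50)))
  kept2 <- density_keypoint_extraction(with_out, 3, interior * 0.6, 2)
  expect_false((n + 1L) %in% attr(kept2, "indices"))

  ident <- density_keypoint_extraction(ball, 3, Inf, 0)
  expect_equal(n_points(ident), n)
})

test_that("body length spans the shoulder and ischial ends", {
  cow <- test_cow(seed = 86)
  bl <- measure_body_length(cow_part(cow, 4), cow_part(cow, 6))
  expect_equal(bl$value, cow$truth[["BL"]],
               tolerance = 0.03 * cow$truth[["BL"]])
  expect_lt(bl$p5[["x"]], bl$p6[["x"]])

  # two separated end caps cluster trivially
  set.seed(87)
  capD <- cbind(rnorm(100, -80, 2), rnorm(100, 0, 5), rnorm(100, 100, 5))
  capE <- cbind(rnorm(100, 80, 2), rnorm(100, 0, 5), rnorm(100, 100, 5))
  bl2 <- measure_body_length(point_cloud(capD), point_cloud(capE),
                             thresholds = c(Inf, 0))
  expect_equal(bl2$value,
               max(dist(rbind(capD[which.min(capD[, 1]), ],
                              capE[which.max(capE[, 1]), ]))),
               tolerance = 1)

  # bent posture: error at most twice the straight-posture error
  straight <- test_cow(seed = 88, points_body = 12000)
  bent <- generate_cow(cow_spec(seed = 88, points_body = 12000,
                                bend_angle = 12))
  err_s <- abs(measure_body_length(cow_part(straight, 4),
                                   cow_part(straight, 6))$value -
                 straight$truth[["BL"]]) / straight$truth[["BL"]]
  err_b <- abs(measure_body_length(cow_part(bent, 4),
                                   cow_part(bent, 6))$value -
                 bent$truth[["BL"]]) / bent$truth[["BL"]]
  expect_lt(err_b, max(2 * err_s, 0.02))
})

test_that("relative error rounds half-up to two decimals", {
  expect_identical(relative_error(100, 100), 0)
  expect_identical(relative_error(200, 201), 0.5)
  expect_identical(relative_error(100, 100.125), 0.13)  # half-up
})

test_that("measure_all reports all parameters and survives failures", {
  cow <- test_cow(seed = 89)
  rep <- measure_all(cow$cloud)
  expect_true(all(!is.na(rep$values)))
  re <- relative_error(cow$truth, rep$values[names(cow$truth)])
  expect_true(all(re <= 3))

  # a missing part fails only its own parameter
  no_mid <- subset_cloud(cow$cloud, cow$cloud$labels != 5L)
  rep2 <- measure_all(no_mid)
  expect_true(is.na(rep2$values[["AC"]]))
  expect_false(is.na(rep2$values[["WH"]]))
  expect_true("AC" %in% names(rep2$diagnostics$errors))

  # JSON round trip
  path <- tempfile(fileext = ".json")
  write_report(rep, path, id = "cow-89")
  back <- read_report(path)
  expect_equal(back$values, rep$values, tolerance = 1e-12)
})

test_that("measurements are translation invariant and scale linearly", {
  cow <- test_cow(seed = 90)
  rep <- measure_all(cow$cloud)

  shifted <- cow$cloud
  shifted$points <- sweep(shifted$points, 2, c(31, -17, 23), `+`)
  rep_s <- measure_all(shifted)
  expect_equal(rep_s$values, rep$values, tolerance = 1e-6)

  scaled <- cow$cloud
  scaled$points <- cow$cloud$points * 1.5
  rep_2 <- measure_all(scaled)
  expect_equal(unname(rep_2$values / rep$values), rep(1.5, 6),
               tolerance = 0.015)
})
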