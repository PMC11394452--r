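tiny_config <- function() {
  network_config(sa_stages = list(
                   list(n1 = 32L, radius = 0.3, K = 8L, mlp = c(8L, 16L)),
                   list(n1 = 8L, radius = 0.6, K = 8L, mlp = c(16L, 32L))),
                 fp_mlp = c(32L, 32L), leaf_capacity = 16L,
                 learning_rate = 2e-2)
}

test_that("IDW interpolation matches the direct formula", {
  set.seed(31)
  known <- matrix(runif(60, -5, 5), ncol = 3)
  feats <- matrix(rnorm(20 * 4), ncol = 4)
  query <- matrix(runif(30, -5, 5), ncol = 3)

  got <- idw_interpolate(known, feats, query, k = 3, p = 2)
  expect_equal(got, naive_idw(known, feats, query, 3, 2),
               tolerance = 1e-9)
  got4 <- idw_interpolate(known, feats, query, k = 5, p = 1)
  expect_equal(got4, naive_idw(known, feats, query, 5, 1),
               tolerance = 1e-9)

  # d = 0 branch: a query on a known point copies its feature exactly
  got2 <- idw_interpolate(known, feats, known[7, , drop = FALSE], k = 3)
  expect_identical(unname(got2[1, ]), unname(feats[7, ]))

  # equidistant pair, k = 2: arithmetic mean
  kp <- rbind(c(-1, 0, 0), c(1, 0, 0))
  kf <- rbind(c(2, 10), c(4, 30))
  expect_equal(idw_interpolate(kp, kf, rbind(c(0, 3, 1)), k = 2)[1, ],
               c(3, 20))

  # convexity: output within the per-dimension range of the k neighbours
  got5 <- idw_interpolate(known, feats, query, k = 4, p = 2)
  expect_true(all(got5 >= min(feats) - 1e-12 &
                    got5 <= max(feats) + 1e-12))

  # k beyond the known count clamps
  expect_silent(idw_interpolate(known[1:2, ], feats[1:2, ], query, k = 10))
})

test_that("cross-entropy loss matches the analytic formula", {
  one_hot <- diag(7)[c(1, 4, 7), ]
  expect_equal(cross_entropy_loss(one_hot, c(0, 3, 6)), 0)

  unif <- matrix(1 / 7, 5, 7)
  expect_equal(cross_entropy_loss(unif, c(0, 1, 2, 3, 4)), log(7),
               tolerance = 1e-9)

  set.seed(5)
  probs <- matrix(runif(21), 3, 7)
  probs <- probs / rowSums(probs)
  y <- c(2L, 0L, 6L)
  hand <- -mean(log(c(probs[1, 3], probs[2, 1], probs[3, 7])))
  expect_equal(cross_entropy_loss(probs, y), hand, tolerance = 1e-9)

  expect_error(cross_entropy_loss(matrix(c(0.9, 0.3), 1, 2), 0), "sum")
})

test_that("OA and mIoU follow the confusion-matrix definitions", {
  y <- rep(0:6, each = 5)
  ev <- evaluate_segmentation(y, y)
  expect_equal(ev$oa, 1)
  expect_equal(ev$miou, 1)

  wrong <- (y + 1L) %% 7L
  expect_equal(evaluate_segmentation(wrong, y)$oa, 0)

  # hand-computed 3-class confusion table [[2,1,0],[0,3,0],[1,0,3]]
  truth <- c(rep(0, 3), rep(1, 3), rep(2, 4))
  pred <- c(0, 0, 1, 1, 1, 1, 0, 2, 2, 2)
  ev3 <- evaluate_segmentation(pred, truth, num_classes = 3)
  expect_equal(unclass(ev3$confusion),
               rbind(c(2, 1, 0), c(0, 3, 0), c(1, 0, 3)),
               ignore_attr = TRUE)
  expect_equal(ev3$oa, 8 / 10)
  expect_equal(unname(ev3$iou), c(2 / 4, 3 / 4, 3 / 4))
  expect_equal(ev3$miou, 2 / 3)

  # invariant to point order; bounded in [0, 1]
  set.seed(2)
  ord <- sample(length(truth))
  ev4 <- evaluate_segmentation(pred[ord], truth[ord], num_classes = 3)
  expect_equal(ev4$oa, ev3$oa)
  expect_equal(ev4$miou, ev3$miou)
  expect_true(ev3$oa >= 0 && ev3$oa <= 1 && ev3$miou >= 0 && ev3$miou <= 1)

  # absent classes excluded by default, counted as 1 when requested
  ev5 <- evaluate_segmentation(c(0, 1), c(0, 1), num_classes = 7)
  expect_equal(ev5$miou, 1)
  ev6 <- evaluate_segmentation(c(0, 1), c(0, 1), num_classes = 7,
                               include_absent = TRUE)
  expect_equal(ev6$miou, 1)
})

test_that("set abstraction pools with a permutation-invariant max", {
  set.seed(41)
  W1 <- matrix(rnorm(3 * 8, sd = 0.5), 3, 8)
  W2 <- matrix(rnorm(8 * 4, sd = 0.5), 8, 4)
  weights <- list(W = list(W1, W2), b = list(rep(0, 8), rep(0, 4)))

  # identical points in one group: pooled feature = map of the zero offset
  same <- point_cloud(matrix(1, 8, 3) + 0)
  sa <- set_abstraction(same$points, stage = list(n1 = 1L, radius = 1,
                                                  K = 8L,
                                                  weights = weights))
  zero_map <- pmax(matrix(0, 1, 3) %*% W1, 0) %*% W2
  expect_equal(sa$pooled_features, pmax(zero_map, 0), tolerance = 1e-12)

  # shuffling the cloud leaves the pooled feature set unchanged
  cl <- seeded_cloud(128, 42, spread = 1)
  sa1 <- set_abstraction(cl$points, stage = list(n1 = 16L, radius = 0.8,
                                                 K = 16L,
                                                 weights = weights))
  expect_equal(dim(sa1$pooled_features), c(16L, 4L))
  expect_equal(dim(sa1$center_points), c(16L, 3L))
  set.seed(1)
  perm <- sample(128)
  sa2 <- set_abstraction(cl$points[perm, ],
                         stage = list(n1 = 16L, radius = 0.8, K = 16L,
                                      weights = weights))
  key <- function(s) {
    o <- do.call(order, as.data.frame(round(s$center_points, 9)))
    round(cbind(s$center_points, s$pooled_features)[o, ], 6)
  }
  expect_equal(key(sa2), key(sa1), tolerance = 1e-6)
})

test_that("toy training is deterministic, lowers the loss and memorizes", {
  herd <- generate_dataset(3, seed = 61, points_body = 230, points_leg = 8,
                           noise_sd = 0.5)
  clouds <- lapply(herd, `[[`, "cloud")

  m1 <- train_toy(clouds, tiny_config(), epochs = 8, seed = 5,
                  trace_every = 1)
  m2 <- train_toy(clouds, tiny_config(), epochs = 8, seed = 5,
                  trace_every = 1)
  expect_identical(tail(m1$trace$loss, 1), tail(m2$trace$loss, 1))
  expect_lt(tail(m1$trace$loss, 1), m1$trace$loss[1])

  # single cloud, capacity to memorize: training OA climbs towards 1
  m3 <- train_toy(clouds[1], tiny_config(), epochs = 120, seed = 5,
                  trace_every = 30)
  expect_gte(tail(m3$trace$oa, 1), 0.93)
})

test_that("prediction takes the per-point argmax and checkpoints round-trip", {
  herd <- generate_dataset(2, seed = 62, points_body = 230, points_leg = 8)
  clouds <- lapply(herd, `[[`, "cloud")
  model <- train_toy(clouds, tiny_config(), epochs = 5, seed = 2)

  pred <- predict_labels(model, clouds[[1]])
  expect_s3_class(pred, "labeled_point_cloud")
  expect_length(pred$labels, n_points(clouds[[1]]))
  expect_true(all(pred$labels %in% 0:6))

  path <- tempfile(fileext = ".rds")
  save_model(model, path)
  re <- load_model(path)
  expect_identical(predict_labels(re, clouds[[2]])$labels,
                   predict_labels(model, clouds[[2]])$labels)

  # feature propagation shape contract
  coarse <- matrix(runif(12), 4, 3)
  cf <- matrix(rnorm(8), 4, 2)
  fine <- matrix(runif(30), 10, 3)
  fp <- feature_propagation(coarse, cf, fine,
                            skip_features = matrix(1, 10, 3))
  expect_equal(dim(fp), c(10L, 5L))
})
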