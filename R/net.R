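# Hierarchical point-cloud part-segmentation network (PointNet++ lineage)
# with DUOS sampling in the set-abstraction stages and inverse-distance
# weighted feature propagation. Implemented directly in matrix algebra with
# hand-written gradients and Adam, sized for CPU toy-scale training: the
# sampling/grouping structure does not depend on the weights, so it is
# precomputed once per cloud and every training step is dense linear algebra.

#' Network configuration
#'
#' @param sa_stages list of set-abstraction stages, each a list with `n1`
#'   (number of sampling centres, strictly decreasing across stages),
#'   `radius` (grouping ball radius in normalized units), `K` (group size)
#'   and `mlp` (per-point layer widths).
#' @param fp_mlp widths of the shared map applied after each feature
#'   propagation (one per stage, deepest first).
#' @param k,p feature-propagation interpolation neighbours and inverse
#'   distance power.
#' @param num_classes number of part labels (7: legs 0-3, body 4-6).
#' @param leaf_capacity,density_radius,density_threshold DUOS parameters in
#'   normalized units, see [duos_sample()].
#' @param learning_rate,batch_shuffle Adam step size and whether the cloud
#'   order is reshuffled (deterministically) each epoch.
#' @return a `network_config` list.
#' @export
network_config <- function(sa_stages = list(
                             list(n1 = 256L, radius = 0.2, K = 32L,
                                  mlp = c(32L, 64L)),
                             list(n1 = 64L, radius = 0.4, K = 32L,
                                  mlp = c(64L, 128L))),
                           fp_mlp = c(128L, 128L),
                           k = 3L, p = 2, num_classes = 7L,
                           leaf_capacity = 32L, density_radius = 0.1,
                           density_threshold = 2L,
                           learning_rate = 5e-3, batch_shuffle = TRUE) {
  n1s <- vapply(sa_stages, function(s) as.integer(s$n1), integer(1L))
  if (length(n1s) == 0L) stop("at least one set-abstraction stage required")
  if (any(diff(n1s) >= 0L)) stop("n1 must be strictly decreasing")
  if (length(fp_mlp) != length(sa_stages))
    stop("one fp width per stage required")
  structure(list(sa_stages = sa_stages, fp_mlp = fp_mlp, k = as.integer(k),
                 p = p, num_classes = as.integer(num_classes),
                 leaf_capacity = as.integer(leaf_capacity),
                 density_radius = density_radius,
                 density_threshold = as.integer(density_threshold),
                 learning_rate = learning_rate,
                 batch_shuffle = isTRUE(batch_shuffle)),
            class = "network_config")
}

#' Inverse-distance-weighted feature interpolation
#'
#' Each query feature is the weighted mean of the features of its `k`
#' nearest known points, with weights `1/d^p`. A query coinciding with a
#' known point (d = 0) copies that point's feature exactly. `k` larger than
#' the number of known points is clamped to the available count.
#'
#' @param known_points m x 3 matrix of known positions.
#' @param known_features m x C feature matrix.
#' @param query_points q x 3 matrix of query positions.
#' @param k neighbours used (>= 1).
#' @param p inverse distance power.
#' @return q x C matrix of interpolated features.
#' @export
idw_interpolate <- function(known_points, known_features, query_points,
                            k = 3L, p = 2) {
  S <- idw_weights(as.matrix(query_points), as.matrix(known_points), k, p)
  as.matrix(S %*% as.matrix(known_features))
}

# sparse (q x m) row-stochastic interpolation operator
idw_weights <- function(query, ref, k, p) {
  stopifnot(k >= 1, nrow(ref) >= 1)
  k <- min(as.integer(k), nrow(ref))
  nn <- cpp_knn(query, ref, k)
  d <- nn$dist
  w <- 1 / pmax(d, .Machine$double.xmin)^p
  zero <- d[, 1L] == 0  # exact coincidence: copy that feature
  if (any(zero)) {
    w[zero, ] <- 0
    w[zero, 1L] <- 1
  }
  w <- w / rowSums(w)
  Matrix::sparseMatrix(i = rep(seq_len(nrow(query)), times = k),
                       j = as.vector(nn$idx), x = as.vector(w),
                       dims = c(nrow(query), nrow(ref)))
}

#' Cross-entropy segmentation loss
#'
#' Mean over points of the negative log probability assigned to the true
#' class. Probabilities below `1e-12` are clamped before taking the log.
#'
#' @param probs N x K matrix of class probabilities (rows sum to 1 within
#'   1e-6).
#' @param labels integer vector of true classes in `0:(K-1)`.
#' @return scalar loss.
#' @export
cross_entropy_loss <- function(probs, labels) {
  probs <- as.matrix(probs)
  if (any(probs < 0)) stop("probabilities must be non-negative")
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop("probability rows must sum to 1")
  labels <- as.integer(labels)
  if (length(labels) != nrow(probs)) stop("one label per row required")
  if (any(labels < 0L | labels >= ncol(probs))) stop("label out of range")
  p_true <- probs[cbind(seq_len(nrow(probs)), labels + 1L)]
  mean(-log(pmax(p_true, 1e-12)))
}

#' Segmentation accuracy metrics
#'
#' Overall accuracy is the fraction of correctly labelled points,
#' `sum(p_ii) / sum(p_ij)` over the confusion matrix. Per-class IoU is
#' `p_ii / (row_i + col_i - p_ii)`; mIoU averages IoU over the classes
#' present in truth or prediction (classes absent from both are excluded
#' unless `include_absent = TRUE`, which scores them as IoU 1).
#'
#' @param predictions,truths integer label vectors in `0:(num_classes-1)`.
#' @param num_classes number of classes (default 7).
#' @param include_absent score absent classes as IoU 1 instead of dropping
#'   them from the mean.
#' @return list with `oa`, `miou`, `iou` (per class, NA when absent and
#'   excluded) and `confusion` (rows = truth, columns = prediction).
#' @export
evaluate_segmentation <- function(predictions, truths, num_classes = 7L,
                                  include_absent = FALSE) {
  predictions <- as.integer(predictions)
  truths <- as.integer(truths)
  stopifnot(length(predictions) == length(truths))
  lv <- 0:(num_classes - 1L)
  cm <- table(factor(truths, levels = lv), factor(predictions, levels = lv))
  cm <- unclass(cm)
  total <- sum(cm)
  oa <- sum(diag(cm)) / total
  rs <- rowSums(cm)
  cs <- colSums(cm)
  denom <- rs + cs - diag(cm)
  iou <- ifelse(denom > 0, diag(cm) / denom, NA_real_)
  if (include_absent) {
    miou <- mean(ifelse(is.na(iou), 1, iou))
  } else {
    miou <- mean(iou, na.rm = TRUE)
  }
  list(oa = oa, miou = miou, iou = iou, confusion = cm)
}

## ---- internal dense layers -------------------------------------------------

relu <- function(x) x * (x > 0)

he_init <- function(n_in, n_out) {
  matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
}

# stack of Linear+ReLU layers; weights drawn from params by name prefix
mlp_forward <- function(X, params, prefix, n_layers) {
  A <- X
  cache <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    W <- params[[paste0(prefix, ".W", l)]]
    b <- params[[paste0(prefix, ".b", l)]]
    Z <- A %*% W
    Z <- sweep(Z, 2L, b, `+`)
    cache[[l]] <- list(A = A, Z = Z)
    A <- relu(Z)
  }
  list(out = A, cache = cache)
}

mlp_backward <- function(dA, params, prefix, cache, grads) {
  for (l in rev(seq_along(cache))) {
    W <- params[[paste0(prefix, ".W", l)]]
    dZ <- dA * (cache[[l]]$Z > 0)
    grads[[paste0(prefix, ".W", l)]] <- crossprod(cache[[l]]$A, dZ)
    grads[[paste0(prefix, ".b", l)]] <- colSums(dZ)
    dA <- tcrossprod(dZ, W)
  }
  list(dX = dA, grads = grads)
}

# column-wise max over the K group slots; rows of H are ordered centre-major
# (row = centre + (slot-1) * nc)
maxpool_forward <- function(H, nc, K) {
  C <- ncol(H)
  out <- matrix(0, nc, C)
  am <- matrix(1L, nc, C)
  for (ch in seq_len(C)) {
    M <- matrix(H[, ch], nc, K)
    k <- max.col(M, ties.method = "first")
    am[, ch] <- k
    out[, ch] <- M[cbind(seq_len(nc), k)]
  }
  list(out = out, am = am)
}

maxpool_backward <- function(dOut, am, nc, K) {
  C <- ncol(dOut)
  dH <- matrix(0, nc * K, C)
  rows <- rep(seq_len(nc), times = C) + (as.vector(am) - 1L) * nc
  dH[cbind(rows, rep(seq_len(C), each = nc))] <- as.vector(dOut)
  dH
}

## ---- structure cache -------------------------------------------------------

# Sampling centres, gather operators and interpolation operators for one
# normalized cloud. None of this depends on the weights.
build_structure <- function(P0, cfg) {
  L <- length(cfg$sa_stages)
  sa <- vector("list", L)
  P <- P0
  for (s in seq_len(L)) {
    stg <- cfg$sa_stages[[s]]
    cl <- point_cloud(P)
    samp <- duos_sample(cl, stg$n1, leaf_capacity = cfg$leaf_capacity,
                        max_depth = 10L,
                        density_radius = cfg$density_radius,
                        density_threshold = cfg$density_threshold)
    grp <- group_neighbors(cl, samp$center_indices, stg$radius, stg$K)
    nc <- length(samp$center_indices)
    gather <- Matrix::sparseMatrix(i = seq_len(nc * stg$K),
                                   j = as.vector(grp$indices), x = 1,
                                   dims = c(nc * stg$K, nrow(P)))
    Pnext <- P[samp$center_indices, , drop = FALSE]
    sa[[s]] <- list(centers = samp$center_indices, gather = gather,
                    rel = matrix(grp$rel, nc * stg$K, 3L),
                    nc = nc, K = stg$K, P_in = P, P_out = Pnext)
    P <- Pnext
  }
  # interpolation operators, deepest level first: level L -> L-1 -> ... -> 0
  fp <- vector("list", L)
  for (s in rev(seq_len(L))) {
    fine <- if (s == 1L) P0 else sa[[s - 1L]]$P_out
    fp[[s]] <- idw_weights(fine, sa[[s]]$P_out, cfg$k, cfg$p)
  }
  list(sa = sa, fp = fp, P0 = P0, n = nrow(P0))
}

## ---- forward / backward ----------------------------------------------------

init_params <- function(cfg, seed) {
  set.seed(as.integer(seed))
  params <- list()
  in_dim <- 3L
  sa_out <- integer(length(cfg$sa_stages))
  for (s in seq_along(cfg$sa_stages)) {
    widths <- cfg$sa_stages[[s]]$mlp
    d <- in_dim
    for (l in seq_along(widths)) {
      params[[paste0("sa", s, ".W", l)]] <- he_init(d, widths[l])
      params[[paste0("sa", s, ".b", l)]] <- rep(0, widths[l])
      d <- widths[l]
    }
    sa_out[s] <- d
    in_dim <- 3L + d  # next stage groups rel-xyz plus pooled features
  }
  L <- length(cfg$sa_stages)
  up_dim <- sa_out[L]
  for (s in rev(seq_len(L))) {
    skip_dim <- if (s == 1L) 3L else sa_out[s - 1L]
    params[[paste0("fp", s, ".W1")]] <- he_init(up_dim + skip_dim,
                                                cfg$fp_mlp[s])
    params[[paste0("fp", s, ".b1")]] <- rep(0, cfg$fp_mlp[s])
    up_dim <- cfg$fp_mlp[s]
  }
  params[["head.W"]] <- he_init(up_dim, cfg$num_classes) * 0.1
  params[["head.b"]] <- rep(0, cfg$num_classes)
  params
}

net_forward <- function(struct, params, cfg, keep_cache = FALSE) {
  L <- length(struct$sa)
  sa_feats <- vector("list", L)
  cache <- list(sa = vector("list", L), fp = vector("list", L))
  Fcur <- NULL
  for (s in seq_len(L)) {
    st <- struct$sa[[s]]
    X <- if (is.null(Fcur)) st$rel else
      cbind(st$rel, as.matrix(st$gather %*% Fcur))
    nl <- length(cfg$sa_stages[[s]]$mlp)
    mf <- mlp_forward(X, params, paste0("sa", s), nl)
    pool <- maxpool_forward(mf$out, st$nc, st$K)
    sa_feats[[s]] <- pool$out
    if (keep_cache)
      cache$sa[[s]] <- list(mlp = mf$cache, am = pool$am, n_layers = nl)
    Fcur <- pool$out
  }
  Fup <- sa_feats[[L]]
  for (s in rev(seq_len(L))) {
    interp <- as.matrix(struct$fp[[s]] %*% Fup)
    skip <- if (s == 1L) struct$P0 else sa_feats[[s - 1L]]
    X <- cbind(interp, skip)
    mf <- mlp_forward(X, params, paste0("fp", s), 1L)
    if (keep_cache)
      cache$fp[[s]] <- list(mlp = mf$cache, up_dim = ncol(interp))
    Fup <- mf$out
  }
  logits <- sweep(Fup %*% params[["head.W"]], 2L, params[["head.b"]], `+`)
  list(logits = logits, feats = Fup, sa_feats = sa_feats,
       cache = if (keep_cache) cache else NULL)
}

net_backward <- function(struct, params, cfg, fwd, dlogits) {
  grads <- list()
  grads[["head.W"]] <- crossprod(fwd$feats, dlogits)
  grads[["head.b"]] <- colSums(dlogits)
  dF <- tcrossprod(dlogits, params[["head.W"]])
  L <- length(struct$sa)
  dskip <- vector("list", L)  # gradient flowing into sa_feats via skips
  for (s in seq_len(L)) {
    mb <- mlp_backward(dF, params, paste0("fp", s),
                       fwd$cache$fp[[s]]$mlp, grads)
    grads <- mb$grads
    up_dim <- fwd$cache$fp[[s]]$up_dim
    dinterp <- mb$dX[, seq_len(up_dim), drop = FALSE]
    if (s > 1L)
      dskip[[s - 1L]] <- mb$dX[, -seq_len(up_dim), drop = FALSE]
    dF <- as.matrix(Matrix::crossprod(struct$fp[[s]], dinterp))
    # dF now flows into sa_feats[[s]]: for s == L it is the direct path,
    # for s < L it combines with the skip gradient captured above
  }
  # walk the SA stages top-down: deepest first
  dsa <- vector("list", L)
  dsa[[L]] <- dF
  for (s in seq_len(L - 1L)) dsa[[s]] <- dskip[[s]]
  dnext <- NULL
  for (s in rev(seq_len(L))) {
    st <- struct$sa[[s]]
    dOut <- dsa[[s]]
    if (!is.null(dnext)) dOut <- dOut + dnext
    dH <- maxpool_backward(dOut, fwd$cache$sa[[s]]$am, st$nc, st$K)
    mb <- mlp_backward(dH, params, paste0("sa", s),
                       fwd$cache$sa[[s]]$mlp, grads)
    grads <- mb$grads
    if (s > 1L) {
      dXfeat <- mb$dX[, -(1:3), drop = FALSE]
      dprev <- as.matrix(Matrix::crossprod(st$gather, dXfeat))
      dnext <- dprev
    }
  }
  grads
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## ---- public training surface ----------------------------------------------

#' Set abstraction (sampling + grouping + shared map + max pooling)
#'
#' Functional single-stage forward pass: DUOS-sampled centres, ball groups,
#' a shared per-point map applied to centred coordinates (concatenated with
#' input features when present), then channel-wise max pooling.
#'
#' @param points n x 3 coordinate matrix (normalized units).
#' @param features optional n x C input feature matrix.
#' @param stage list with `n1`, `radius`, `K` and `weights` (list of `W`
#'   matrices and `b` vectors for the shared map).
#' @param duos list of DUOS parameters (`leaf_capacity`, `density_radius`,
#'   `density_threshold`).
#' @return list with `center_points` (n1 x 3) and `pooled_features`.
#' @export
set_abstraction <- function(points, features = NULL, stage,
                            duos = list(leaf_capacity = 32L,
                                        density_radius = 0.1,
                                        density_threshold = 2L)) {
  points <- as.matrix(points)
  cl <- point_cloud(points)
  if (stage$n1 > nrow(points)) stop("stage n1 exceeds the point count")
  samp <- duos_sample(cl, stage$n1, leaf_capacity = duos$leaf_capacity,
                      density_radius = duos$density_radius,
                      density_threshold = duos$density_threshold)
  grp <- group_neighbors(cl, samp$center_indices, stage$radius, stage$K)
  nc <- length(samp$center_indices)
  X <- matrix(grp$rel, nc * stage$K, 3L)
  if (!is.null(features)) {
    features <- as.matrix(features)
    X <- cbind(X, features[as.vector(grp$indices), , drop = FALSE])
  }
  params <- list()
  for (l in seq_along(stage$weights$W)) {
    params[[paste0("sa.W", l)]] <- stage$weights$W[[l]]
    params[[paste0("sa.b", l)]] <- stage$weights$b[[l]]
  }
  H <- mlp_forward(X, params, "sa", length(stage$weights$W))$out
  pool <- maxpool_forward(H, nc, stage$K)
  list(center_points = points[samp$center_indices, , drop = FALSE],
       pooled_features = pool$out, center_indices = samp$center_indices)
}

#' Feature propagation (IDW upsampling + skip concatenation + shared map)
#'
#' @param coarse_points,coarse_features coarse level positions/features.
#' @param fine_points fine level positions.
#' @param skip_features optional fine-level features concatenated after
#'   interpolation.
#' @param weights list with `W` matrix and `b` vector of the shared map
#'   (pass `NULL` to return the concatenated features unmapped).
#' @param k,p interpolation parameters, see [idw_interpolate()].
#' @return fine-level feature matrix.
#' @export
feature_propagation <- function(coarse_points, coarse_features, fine_points,
                                skip_features = NULL, weights = NULL,
                                k = 3L, p = 2) {
  up <- idw_interpolate(coarse_points, coarse_features, fine_points, k, p)
  X <- if (is.null(skip_features)) up else cbind(up, as.matrix(skip_features))
  if (is.null(weights)) return(X)
  relu(sweep(X %*% weights$W, 2L, weights$b, `+`))
}

# normalize a labelled cloud and precompute its network structure
prepare_cloud <- function(lcl, cfg) {
  norm <- normalize_cloud(lcl)
  list(struct = build_structure(norm$cloud$points, cfg),
       labels = lcl$labels)
}

#' Train the toy segmentation network
#'
#' Full-gradient Adam over the clouds of `dataset` (one step per cloud per
#' epoch), deterministic given `seed`. Sampling structures are precomputed
#' per cloud.
#'
#' @param dataset list of `labeled_point_cloud`s.
#' @param config a [network_config()].
#' @param epochs training epochs.
#' @param seed integer seed (initialization and epoch shuffling).
#' @param trace_every evaluate training OA every this many epochs.
#' @param verbose print per-epoch progress.
#' @return a `bovimetry_model`: list with `params`, `config` and `trace`
#'   (data.frame epoch, loss, oa).
#' @export
train_toy <- function(dataset, config = network_config(), epochs = 50L,
                      seed = 1L, trace_every = 5L, verbose = FALSE) {
  stopifnot(length(dataset) >= 1L)
  prepped <- lapply(dataset, prepare_cloud, cfg = config)
  params <- init_params(config, seed)
  state <- list(m = list(), v = list())
  t <- 0L
  trace <- data.frame(epoch = integer(0L), loss = numeric(0L),
                      oa = numeric(0L))
  set.seed(as.integer(seed) + 1L)
  order_seeds <- sample.int(.Machine$integer.max, epochs)
  for (ep in seq_len(epochs)) {
    ord <- seq_along(prepped)
    if (config$batch_shuffle && length(prepped) > 1L) {
      set.seed(order_seeds[ep])
      ord <- sample(ord)
    }
    losses <- numeric(0L)
    correct <- 0L
    total <- 0L
    for (i in ord) {
      pc <- prepped[[i]]
      fwd <- net_forward(pc$struct, params, config, keep_cache = TRUE)
      n <- nrow(fwd$logits)
      lg <- fwd$logits - apply(fwd$logits, 1L, max)
      probs <- exp(lg) / rowSums(exp(lg))
      y <- pc$labels
      losses <- c(losses, mean(-log(pmax(
        probs[cbind(seq_len(n), y + 1L)], 1e-12))))
      pred <- max.col(probs, ties.method = "first") - 1L
      correct <- correct + sum(pred == y)
      total <- total + n
      Y <- matrix(0, n, config$num_classes)
      Y[cbind(seq_len(n), y + 1L)] <- 1
      dlogits <- (probs - Y) / n
      grads <- net_backward(pc$struct, params, config, fwd, dlogits)
      t <- t + 1L
      upd <- adam_step(params, grads, state, config$learning_rate, t)
      params <- upd$params
      state <- upd$state
    }
    if (ep %% trace_every == 0L || ep == epochs || ep == 1L) {
      trace <- rbind(trace, data.frame(epoch = ep, loss = mean(losses),
                                       oa = correct / total))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  oa %.4f",
                        ep, mean(losses), correct / total))
    }
  }
  structure(list(params = params, config = config, trace = trace,
                 seed = as.integer(seed)),
            class = "bovimetry_model")
}

#' Predict part labels for a cloud
#'
#' Runs the trained network on a (raw, cm-scale) cloud: the cloud is
#' normalized, sampling structure built, and the per-point 7-way argmax
#' taken (ties resolved to the lowest class index).
#'
#' @param model a `bovimetry_model` from [train_toy()].
#' @param cloud a `point_cloud`.
#' @return a `labeled_point_cloud` carrying the predicted labels.
#' @export
predict_labels <- function(model, cloud) {
  norm <- normalize_cloud(cloud)
  struct <- build_structure(norm$cloud$points, model$config)
  fwd <- net_forward(struct, model$params, model$config)
  pred <- max.col(fwd$logits, ties.method = "first") - 1L
  labeled_point_cloud(point_cloud(cloud$points, cloud$features), pred)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive embedding the weights, the full
#' network configuration, the seed and the metric trace; reloading yields
#' bit-identical predictions.
#'
#' @param model a `bovimetry_model`.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "bovimetry_model")) stop("not a bovimetry checkpoint")
  model
}
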