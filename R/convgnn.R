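#' Multi-channel omics tensor aligned to a graph's node order
#'
#' @param x n x p matrix (single channel), list of such matrices, or an
#'   n x p x C array; columns must follow the graph node order used downstream.
#' @param labels binary vector (0/1, or a 2-level factor) of length n.
#' @param channel_names optional names for the omics channels.
#' @param node_ids optional node identifiers (taken from column names when
#'   present).
#' @return object of class `omics_tensor` with `x` (n x p x C array),
#'   `labels`, `channel_names`, `node_ids`.
#' @export
omics_tensor <- function(x, labels, channel_names = NULL, node_ids = NULL) {
  if (is.list(x) && !is.array(x)) {
    mats <- lapply(x, as.matrix)
    dims <- unique(lapply(mats, dim))
    if (length(dims) != 1) stop("all channels must share dimensions")
    if (is.null(node_ids)) node_ids <- colnames(mats[[1]])
    if (is.null(channel_names)) channel_names <- names(x)
    x <- array(unlist(mats), c(dim(mats[[1]]), length(mats)))
  } else if (length(dim(x)) == 2) {
    if (is.null(node_ids)) node_ids <- colnames(x)
    x <- array(as.matrix(x), c(dim(x), 1))
  }
  n <- dim(x)[1]; C <- dim(x)[3]
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  if (length(labels) != n) stop("labels must match the number of samples")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (anyNA(x)) stop("omics values must not contain missing values")
  if (is.null(channel_names)) channel_names <- sprintf("channel%d", seq_len(C))
  if (is.null(node_ids)) node_ids <- sprintf("n%04d", seq_len(dim(x)[2]))
  structure(list(x = x, labels = labels, channel_names = channel_names,
                 node_ids = node_ids),
            class = "omics_tensor")
}

#' Feature-wise z-standardization with training-set statistics
#'
#' Standardizes each feature in each channel to mean 0, standard deviation 1
#' (sample SD, n - 1), computing the statistics on `train_idx` only and
#' applying them to every sample — validation/test rows never leak into the
#' scaler. Features with SD below 1e-12 are centered only, with a warning.
#'
#' @param tensor an [omics_tensor()].
#' @param train_idx rows used to estimate means/SDs (default: all rows).
#' @return the standardized `omics_tensor`, with the scaler stored in
#'   `$scaler` (`center`, `scale` matrices p x C) for reuse on new data.
#' @export
standardize_omics <- function(tensor, train_idx = NULL) {
  x <- tensor$x
  n <- dim(x)[1]; p <- dim(x)[2]; C <- dim(x)[3]
  if (is.null(train_idx)) train_idx <- seq_len(n)
  if (length(train_idx) < 2) stop("need at least 2 training samples")
  center <- matrix(0, p, C)
  scale <- matrix(1, p, C)
  n_const <- 0L
  for (c in seq_len(C)) {
    xc <- x[train_idx, , c, drop = FALSE]
    mu <- colMeans(matrix(xc, length(train_idx), p))
    sd <- apply(matrix(xc, length(train_idx), p), 2, stats::sd)
    const <- sd < 1e-12
    n_const <- n_const + sum(const)
    sd[const] <- 1
    center[, c] <- mu
    scale[, c] <- sd
    x[, , c] <- .cmul(.csub(matrix(x[, , c], n, p), mu), 1 / sd)
  }
  if (n_const > 0)
    warning(sprintf("%d constant feature(s) centered but not scaled", n_const))
  tensor$x <- x
  tensor$scaler <- list(center = center, scale = scale)
  tensor
}

# apply a stored scaler to a raw n x p x C array
apply_scaler <- function(x, scaler) {
  for (c in seq_len(dim(x)[3]))
    x[, , c] <- sweep(sweep(x[, , c], 2, scaler$center[, c]), 2,
                      scaler$scale[, c], "/")
  x
}

#' Flatten an omics tensor to a samples x (nodes * channels) matrix
#'
#' Channel-major layout: all nodes of channel 1, then all nodes of channel 2,
#' etc. Column names are `<node>_<channel>`. This is the feature space seen by
#' the non-graph baselines and the Shapley explainer.
#' @param tensor an [omics_tensor()].
#' @return n x (p * C) numeric matrix.
#' @export
flatten_tensor <- function(tensor) {
  d <- dim(tensor$x)
  out <- matrix(tensor$x, d[1], d[2] * d[3])
  colnames(out) <- as.vector(outer(tensor$node_ids, tensor$channel_names,
                                   paste, sep = "_"))
  out
}

#' Stratified test split plus k-fold assignment of the remainder
#'
#' Holds out `floor(test_frac * n)` samples as the fixed test set (stratified
#' by label) and partitions the remaining samples into `folds`
#' label-stratified cross-validation folds whose sizes differ by at most one.
#'
#' @param labels binary labels, length n >= 10.
#' @param seed RNG seed; identical seeds give identical plans.
#' @param test_frac held-out fraction, default 0.2.
#' @param folds number of CV folds, default 4.
#' @return object of class `split_plan`: `test` (indices), `fold` (fold id
#'   per non-test sample, NA for test rows), `folds`, `seed`.
#' @export
make_split_plan <- function(labels, seed = 1L, test_frac = 0.2, folds = 4L) {
  n <- length(labels)
  if (n < 10) stop("need at least 10 samples")
  m <- floor(test_frac * n)
  with_seed(seed, {
    classes <- sort(unique(labels))
    # allocate test counts per class: floor shares, remainder by fractional part
    n_c <- vapply(classes, function(k) sum(labels == k), integer(1))
    share <- m * n_c / n
    m_c <- floor(share)
    rem <- m - sum(m_c)
    if (rem > 0) {
      o <- order(share - m_c, decreasing = TRUE)
      m_c[o[seq_len(rem)]] <- m_c[o[seq_len(rem)]] + 1
    }
    test <- integer(0)
    for (ci in seq_along(classes))
      test <- c(test, sample(which(labels == classes[ci]), m_c[ci]))
    test <- sort(test)
    fold <- rep(NA_integer_, n)
    counter <- 0L
    for (ci in seq_along(classes)) {
      idx <- sample(setdiff(which(labels == classes[ci]), test))
      fold[idx] <- (counter + seq_along(idx) - 1L) %% folds + 1L
      counter <- counter + length(idx)
    }
  })
  for (f in seq_len(folds)) {
    lf <- labels[which(fold == f)]
    if (length(unique(lf)) < length(unique(labels)))
      stop(sprintf("stratification failed: a class is absent from fold %d", f))
  }
  structure(list(test = test, fold = fold, folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' Model configuration with the published defaults
#'
#' Defaults reproduce the reference architecture and optimizer settings: two
#' graph-convolution layers of 32 Chebyshev filters with polynomial sizes 10
#' and 2, pooling 2 after each, two fully connected layers of 64 units,
#' softmax output; dropout 0.3, L2 5e-4, Adam with learning rate 0.001
#' decayed by 0.95 every 10 optimizer steps (staircase), 25 epochs,
#' early-stopping patience 5 on validation loss. Batch size (64) and patience
#' are unstated in the source protocol and configurable here.
#'
#' @param conv_filters filters per graph-conv layer.
#' @param cheb_order Chebyshev polynomial count per layer (filter size).
#' @param pool pooling size per layer.
#' @param fc hidden fully-connected layer widths.
#' @param dropout,l2,lr,decay_rate,decay_step,epochs,batch_size,patience
#'   training hyper-parameters (see description).
#' @param pooling `"average"` (fakes count as zeros) or `"real_average"`.
#' @param laplacian `"combinatorial"` or `"normalized"`.
#' @param channel_mode `"shared"` (shared conv kernels, per-channel passes,
#'   concatenation before the FC stack) or `"joint"` (channels as joint input
#'   channels of one filter bank).
#' @param folds CV folds, `seed` global RNG seed.
#' @return a `model_config` list.
#' @export
model_config <- function(conv_filters = c(32L, 32L),
                         cheb_order = c(10L, 2L),
                         pool = c(2L, 2L),
                         fc = c(64L, 64L),
                         dropout = 0.3, l2 = 5e-4,
                         lr = 1e-3, decay_rate = 0.95, decay_step = 10L,
                         epochs = 25L, batch_size = 64L, patience = 5L,
                         pooling = c("average", "real_average"),
                         laplacian = c("combinatorial", "normalized"),
                         channel_mode = c("shared", "joint"),
                         folds = 4L, seed = 1L) {
  stopifnot(length(conv_filters) == length(cheb_order),
            length(conv_filters) == length(pool))
  structure(list(conv_filters = as.integer(conv_filters),
                 cheb_order = as.integer(cheb_order),
                 pool = as.integer(pool), fc = as.integer(fc),
                 dropout = dropout, l2 = l2, lr = lr,
                 decay_rate = decay_rate, decay_step = as.integer(decay_step),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 pooling = match.arg(pooling),
                 laplacian = match.arg(laplacian),
                 channel_mode = match.arg(channel_mode),
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "model_config")
}

# scaled Laplacian of one (padded, position-ordered) hierarchy level
scaled_level_laplacian <- function(adj, kind) {
  g <- weighted_graph(sprintf("v%06d", seq_len(nrow(adj))), adj,
                      sort_nodes = FALSE)
  L <- build_laplacian(g, kind)
  if (L$lambda_max <= 1e-12)
    return(-Matrix::Diagonal(nrow(adj)))   # edgeless level: L = 0, limit map
  scale_laplacian(L)
}

#' Build an untrained graph-convolutional classifier
#'
#' Architecture per omics channel: input batch normalization, then per conv
#' layer (Chebyshev filter -> batch normalization -> ReLU -> average pool);
#' channel feature maps are concatenated (channel-major), flattened, and fed
#' through the FC stack to a 2-class softmax. Convolution kernels and all
#' trainable parameters are shared across channels; batch statistics are
#' tracked per channel. Weights are He-initialized under the config seed.
#'
#' @param config a [model_config()].
#' @param hierarchy a [graclus_coarsen()] hierarchy at least as deep as the
#'   number of conv layers, with matching pool size.
#' @param n_channels number of omics channels the model will see.
#' @return object of class `gcn_model` (untrained) including a
#'   `param_report` data frame of per-layer parameter counts.
#' @export
build_model <- function(config, hierarchy, n_channels) {
  n_conv <- length(config$conv_filters)
  if (hierarchy$levels < n_conv)
    stop("hierarchy depth is smaller than the number of conv layers")
  if (any(config$pool != hierarchy$pool_size))
    stop("config pool sizes do not match the hierarchy pool size")
  joint <- config$channel_mode == "joint"
  sizes <- hierarchy$sizes
  scaled_L <- lapply(seq_len(n_conv), function(l)
    scaled_level_laplacian(hierarchy$graphs[[l]], config$laplacian))
  plan <- pool_plan(hierarchy,
                    if (config$pooling == "average") "average" else "real_average")
  pool_w <- lapply(plan$ops, function(P) {     # per-position pooling weights
    w <- numeric(nrow(P))
    ij <- Matrix::which(P != 0, arr.ind = TRUE)
    w[ij[, 1]] <- P[ij]
    w
  })
  C_in <- c(if (joint) n_channels else 1L,
            config$conv_filters[-n_conv])
  p_out <- sizes[n_conv + 1]
  F_out <- config$conv_filters[n_conv]
  d_in <- (if (joint) 1L else n_channels) * p_out * F_out
  params <- list()
  params$bn_in_gamma <- rep(1, sizes[1])
  params$bn_in_beta <- rep(0, sizes[1])
  with_seed(config$seed, {
    for (l in seq_len(n_conv)) {
      K <- config$cheb_order[l]
      fan_in <- K * C_in[l]
      params[[sprintf("conv%d_theta", l)]] <-
        array(stats::rnorm(K * C_in[l] * config$conv_filters[l],
                           sd = sqrt(2 / fan_in)),
              c(K, C_in[l], config$conv_filters[l]))
      params[[sprintf("conv%d_bias", l)]] <- rep(0, config$conv_filters[l])
      params[[sprintf("bn%d_gamma", l)]] <- rep(1, config$conv_filters[l])
      params[[sprintf("bn%d_beta", l)]] <- rep(0, config$conv_filters[l])
    }
    widths <- c(d_in, config$fc, 2L)
    for (l in seq_len(length(widths) - 1)) {
      params[[sprintf("fc%d_W", l)]] <-
        matrix(stats::rnorm(widths[l] * widths[l + 1],
                            sd = sqrt(2 / widths[l])),
               widths[l], widths[l + 1])
      params[[sprintf("fc%d_b", l)]] <- rep(0, widths[l + 1])
    }
  })
  state <- list(bn_in = replicate(n_channels, list(
    mean = rep(0, sizes[1]), var = rep(1, sizes[1])), simplify = FALSE))
  for (l in seq_len(n_conv))
    state[[sprintf("bn%d", l)]] <- replicate(n_channels, list(
      mean = rep(0, config$conv_filters[l]),
      var = rep(1, config$conv_filters[l])), simplify = FALSE)
  report <- data.frame(
    layer = c(sprintf("conv%d", seq_len(n_conv)),
              sprintf("fc%d", seq_along(config$fc)), "softmax"),
    weights = c(vapply(seq_len(n_conv), function(l)
      config$cheb_order[l] * C_in[l] * config$conv_filters[l], numeric(1)),
      utils::head(c(d_in, config$fc), length(config$fc)) * config$fc,
      utils::tail(config$fc, 1) * 2),
    biases = c(config$conv_filters, config$fc, 2))
  structure(list(kind = "gcn", params = params, state = state,
                 config = config, hierarchy = hierarchy, scaled_L = scaled_L,
                 pool = plan, pool_w = pool_w, n_channels = n_channels,
                 n_conv = n_conv, d_in = d_in, param_report = report,
                 trained = FALSE),
            class = "gcn_model")
}

#' Build an untrained multi-layer perceptron on flattened features
#'
#' The non-graph reference network: the same FC stack, dropout, L2 and
#' optimizer settings as the graph model, but on flattened
#' (nodes x channels) features with no convolution and no graph.
#'
#' @param config a [model_config()] (conv settings ignored).
#' @param n_features flattened input width (p * C).
#' @return object of class `gcn_model` with `kind = "mlp"`.
#' @export
build_mlp <- function(config, n_features) {
  params <- list()
  with_seed(config$seed, {
    widths <- c(n_features, config$fc, 2L)
    for (l in seq_len(length(widths) - 1)) {
      params[[sprintf("fc%d_W", l)]] <-
        matrix(stats::rnorm(widths[l] * widths[l + 1],
                            sd = sqrt(2 / widths[l])),
               widths[l], widths[l + 1])
      params[[sprintf("fc%d_b", l)]] <- rep(0, widths[l + 1])
    }
  })
  structure(list(kind = "mlp", params = params, state = list(),
                 config = config, n_features = n_features, trained = FALSE),
            class = "gcn_model")
}

# stride pooling of an n x m x F activation: positions are contiguous sibling
# blocks, so pooling is a strided weighted sum (no permutation, no sparse op)
fast_pool <- function(h, w, ps) pool_cpp(h, w, ps)

fast_unpool <- function(dp, w, ps, m) unpool_cpp(dp, w, ps, m)

# full forward pass; X_pad is B x p0 x C, already standardized and padded to
# the hierarchy layout (see pad_signal); MLP input may be any B x p x C shape
gcn_forward <- function(model, params, state, X_pad, training = FALSE) {
  config <- model$config
  if (model$kind == "mlp") {
    x <- matrix(X_pad, dim(X_pad)[1], prod(dim(X_pad)[-1]))
    caches <- list()
    h <- x
    nfc <- length(config$fc) + 1L
    for (l in seq_len(nfc)) {
      fcc <- fc_forward(h, params[[sprintf("fc%d_W", l)]],
                        params[[sprintf("fc%d_b", l)]])
      h <- fcc$y
      caches[[sprintf("fc%d", l)]] <- fcc
      if (l < nfc) {
        rl <- relu_forward(h); h <- rl$y
        caches[[sprintf("relu%d", l)]] <- rl
        dp <- dropout_forward(h, config$dropout, training); h <- dp$y
        caches[[sprintf("drop%d", l)]] <- dp
      }
    }
    return(list(logits = h, caches = caches, state = state))
  }
  joint <- config$channel_mode == "joint"
  Xp <- X_pad
  B <- dim(Xp)[1]
  chans <- if (joint) list(Xp) else lapply(seq_len(dim(Xp)[3]),
                                           function(c) Xp[, , c, drop = FALSE])
  if (!training)
    return(gcn_forward_eval(model, params, state, chans, joint))
  ch_caches <- vector("list", length(chans))
  flats <- vector("list", length(chans))
  for (ci in seq_along(chans)) {
    cc <- list()
    xc <- chans[[ci]]
    # input batch norm, per node, parameters shared across channels
    nC <- dim(xc)[3]
    for (cl in seq_len(nC)) {
      si <- if (joint) cl else ci       # per-omics-channel running stats
      bn <- bn_forward(matrix(xc[, , cl], B), params$bn_in_gamma,
                       params$bn_in_beta, training,
                       state$bn_in[[si]]$mean, state$bn_in[[si]]$var)
      xc[, , cl] <- bn$y
      if (training) {
        state$bn_in[[si]]$mean <- bn$run_mean
        state$bn_in[[si]]$var <- bn$run_var
      }
      cc[[sprintf("bn_in_%d", cl)]] <- bn$cache
    }
    h <- xc
    for (l in seq_len(model$n_conv)) {
      cv <- cheb_conv_forward(h, model$scaled_L[[l]],
                              params[[sprintf("conv%d_theta", l)]],
                              params[[sprintf("conv%d_bias", l)]])
      hmat <- matrix(cv$y, B * dim(cv$y)[2], dim(cv$y)[3])
      bn <- bn_forward(hmat, params[[sprintf("bn%d_gamma", l)]],
                       params[[sprintf("bn%d_beta", l)]], training,
                       state[[sprintf("bn%d", l)]][[ci]]$mean,
                       state[[sprintf("bn%d", l)]][[ci]]$var)
      if (training) {
        state[[sprintf("bn%d", l)]][[ci]]$mean <- bn$run_mean
        state[[sprintf("bn%d", l)]][[ci]]$var <- bn$run_var
      }
      rl <- relu_forward(bn$y)
      act <- array(rl$y, dim(cv$y))
      pooled <- fast_pool(act, model$pool_w[[l]], model$pool$pool_size)
      cc[[sprintf("conv%d", l)]] <- cv
      cc[[sprintf("bn%d", l)]] <- bn$cache
      cc[[sprintf("relu%d", l)]] <- rl
      cc[[sprintf("shape%d", l)]] <- dim(cv$y)
      h <- pooled
    }
    flats[[ci]] <- matrix(h, B, prod(dim(h)[-1]))
    cc$out_dim <- dim(h)
    ch_caches[[ci]] <- cc
  }
  h <- do.call(cbind, flats)
  caches <- list(channels = ch_caches, flat_width = ncol(flats[[1]]))
  nfc <- length(config$fc) + 1L
  for (l in seq_len(nfc)) {
    fcc <- fc_forward(h, params[[sprintf("fc%d_W", l)]],
                      params[[sprintf("fc%d_b", l)]])
    h <- fcc$y
    caches[[sprintf("fc%d", l)]] <- fcc
    if (l < nfc) {
      rl <- relu_forward(h); h <- rl$y
      caches[[sprintf("relu%d", l)]] <- rl
      dp <- dropout_forward(h, config$dropout, training); h <- dp$y
      caches[[sprintf("drop%d", l)]] <- dp
    }
  }
  list(logits = h, caches = caches, state = state)
}

# inference-only forward: eval-mode batch norm is an affine map per filter,
# so it is folded into the convolution weights and biases; no caches kept
gcn_forward_eval <- function(model, params, state, chans, joint) {
  config <- model$config
  eps <- 1e-5
  flats <- vector("list", length(chans))
  for (ci in seq_along(chans)) {
    xc <- chans[[ci]]
    B <- dim(xc)[1]
    nC <- dim(xc)[3]
    for (cl in seq_len(nC)) {
      si <- if (joint) cl else ci
      a <- as.numeric(params$bn_in_gamma) / sqrt(state$bn_in[[si]]$var + eps)
      b <- as.numeric(params$bn_in_beta) - state$bn_in[[si]]$mean * a
      xc[, , cl] <- .cadd(.cmul(matrix(xc[, , cl], B), a), b)
    }
    h <- xc
    for (l in seq_len(model$n_conv)) {
      si <- if (joint) 1L else ci
      st <- state[[sprintf("bn%d", l)]][[si]]
      gamma <- as.numeric(params[[sprintf("bn%d_gamma", l)]])
      beta <- as.numeric(params[[sprintf("bn%d_beta", l)]])
      a <- gamma / sqrt(st$var + eps)
      theta <- params[[sprintf("conv%d_theta", l)]]
      K <- dim(theta)[1]; C_in <- dim(theta)[2]
      thf <- theta * rep(a, each = K * C_in)
      bf <- a * (as.numeric(params[[sprintf("conv%d_bias", l)]]) - st$mean) + beta
      cv <- cheb_conv_forward(h, model$scaled_L[[l]], thf, bf)
      act <- array(relu_cpp(matrix(cv$y, B * dim(cv$y)[2], dim(cv$y)[3])),
                   dim(cv$y))
      h <- fast_pool(act, model$pool_w[[l]], model$pool$pool_size)
    }
    flats[[ci]] <- matrix(h, B, prod(dim(h)[-1]))
  }
  h <- do.call(cbind, flats)
  nfc <- length(config$fc) + 1L
  for (l in seq_len(nfc)) {
    h <- .cadd(h %*% params[[sprintf("fc%d_W", l)]],
               as.numeric(params[[sprintf("fc%d_b", l)]]))
    if (l < nfc) h <- relu_cpp(h)
  }
  list(logits = h, caches = NULL, state = state)
}

gcn_backward <- function(model, params, caches, dlogits) {
  config <- model$config
  grads <- list()
  nfc <- length(config$fc) + 1L
  dh <- dlogits
  for (l in seq(nfc, 1)) {
    if (l < nfc) {
      dp <- caches[[sprintf("drop%d", l)]]
      if (!is.null(dp$mask)) dh <- dh * dp$mask
      dh <- relu_backward_cpp(dh, caches[[sprintf("relu%d", l)]]$y)
    }
    fb <- fc_backward(dh, caches[[sprintf("fc%d", l)]],
                      params[[sprintf("fc%d_W", l)]])
    grads[[sprintf("fc%d_W", l)]] <- fb$dW
    grads[[sprintf("fc%d_b", l)]] <- fb$db
    dh <- fb$dx
  }
  if (model$kind == "mlp") return(grads)
  fw <- caches$flat_width
  for (ci in seq_along(caches$channels)) {
    cc <- caches$channels[[ci]]
    dflat <- dh[, ((ci - 1) * fw + 1):(ci * fw), drop = FALSE]
    dcur <- array(dflat, cc$out_dim)
    for (l in seq(model$n_conv, 1)) {
      shp <- cc[[sprintf("shape%d", l)]]
      dact <- fast_unpool(dcur, model$pool_w[[l]], model$pool$pool_size,
                          shp[2])
      dmat <- matrix(dact, shp[1] * shp[2], shp[3])
      dmat <- relu_backward_cpp(dmat, cc[[sprintf("relu%d", l)]]$y)
      bnb <- bn_backward(dmat, cc[[sprintf("bn%d", l)]])
      grads <- grad_acc(grads, sprintf("bn%d_gamma", l), bnb$dgamma)
      grads <- grad_acc(grads, sprintf("bn%d_beta", l), bnb$dbeta)
      dY <- array(bnb$dx, shp)
      cvb <- cheb_conv_backward(dY, cc[[sprintf("conv%d", l)]],
                                model$scaled_L[[l]],
                                params[[sprintf("conv%d_theta", l)]])
      grads <- grad_acc(grads, sprintf("conv%d_theta", l), cvb$dtheta)
      grads <- grad_acc(grads, sprintf("conv%d_bias", l), cvb$dbias)
      dcur <- cvb$dx
    }
    for (cl in seq_len(dim(dcur)[3])) {
      bnb <- bn_backward(matrix(dcur[, , cl], dim(dcur)[1]),
                         cc[[sprintf("bn_in_%d", cl)]])
      grads <- grad_acc(grads, "bn_in_gamma", bnb$dgamma)
      grads <- grad_acc(grads, "bn_in_beta", bnb$dbeta)
    }
  }
  grads
}

weight_param_names <- function(model) {
  nms <- names(model$params)
  nms[grepl("_W$|_theta$", nms)]
}

#' Train a model with Adam, staircase decay, and early stopping
#'
#' Minimizes cross-entropy plus L2 on the weight matrices. The learning rate
#' is multiplied by `decay_rate` every `decay_step` optimizer steps
#' (staircase). Validation loss is monitored each epoch; training stops after
#' `patience` consecutive non-improving epochs and the best weights are
#' restored. All randomness (shuffling, dropout) derives from the config
#' seed, so identical seeds give identical weights on CPU.
#'
#' @param model an untrained [build_model()] or [build_mlp()] object.
#' @param tensor a standardized [omics_tensor()].
#' @param train_idx,val_idx row indices for training and validation
#'   (`val_idx` may be empty to disable early stopping).
#' @return the trained model, with `$history` (per-epoch train/val loss and
#'   accuracy) and `$best_epoch`.
#' @export
train_model <- function(model, tensor, train_idx, val_idx = integer(0)) {
  config <- model$config
  params <- model$params
  state <- model$state
  opt <- adam_init(params)
  wnames <- weight_param_names(model)
  y <- tensor$labels
  # pad once up front; batches slice the padded array
  Xd <- if (model$kind == "gcn") pad_signal(tensor$x, model$hierarchy)
        else tensor$x
  best <- list(loss = Inf, params = params, state = state, epoch = 0L)
  wait <- 0L
  hist <- NULL
  step <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(train_idx)
      nb <- ceiling(length(ord) / config$batch_size)
      batches <- split(ord, rep(seq_len(nb), each = config$batch_size,
                                length.out = length(ord)))
      if (nb > 1 && length(batches[[nb]]) == 1) {   # avoid 1-row batch norms
        batches[[nb - 1]] <- c(batches[[nb - 1]], batches[[nb]])
        batches[[nb]] <- NULL
      }
      ep_loss <- 0; ep_n <- 0; ep_correct <- 0
      for (b in batches) {
        step <- step + 1L
        lr <- config$lr * config$decay_rate^((step - 1) %/% config$decay_step)
        fwd <- gcn_forward(model, params, state,
                           Xd[b, , , drop = FALSE], training = TRUE)
        state <- fwd$state
        ce <- softmax_ce(fwd$logits, y[b])
        l2pen <- config$l2 * sum(vapply(wnames, function(nm)
          sum(params[[nm]]^2), numeric(1)))
        if (!is.finite(ce$loss))
          stop(sprintf("training diverged (non-finite loss) at epoch %d step %d",
                       epoch, step))
        grads <- gcn_backward(model, params, fwd$caches, ce$dlogits)
        for (nm in wnames)
          grads[[nm]] <- grads[[nm]] + 2 * config$l2 * params[[nm]]
        upd <- adam_step(params, grads, opt, lr)
        params <- upd$params
        opt <- upd$state
        ep_loss <- ep_loss + (ce$loss + l2pen) * length(b)
        ep_n <- ep_n + length(b)
        ep_correct <- ep_correct + sum(max.col(ce$probs) - 1L == y[b])
      }
      tr_loss <- ep_loss / ep_n
      tr_acc <- ep_correct / ep_n
      va_loss <- NA_real_; va_acc <- NA_real_
      if (length(val_idx)) {
        vf <- gcn_forward(model, params, state,
                          Xd[val_idx, , , drop = FALSE], training = FALSE)
        vce <- softmax_ce(vf$logits, y[val_idx])
        va_loss <- vce$loss
        va_acc <- mean(max.col(vce$probs) - 1L == y[val_idx])
      }
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tr_loss,
                                     train_acc = tr_acc, val_loss = va_loss,
                                     val_acc = va_acc))
      if (length(val_idx)) {
        if (va_loss < best$loss - 1e-8) {
          best <- list(loss = va_loss, params = params, state = state,
                       epoch = epoch)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait > config$patience) break
        }
      }
    }
  })
  if (length(val_idx) && best$epoch > 0) {
    model$params <- best$params
    model$state <- best$state
    model$best_epoch <- best$epoch
  } else {
    model$params <- params
    model$state <- state
    model$best_epoch <- nrow(hist)
  }
  model$history <- hist
  model$trained <- TRUE
  model
}

#' Predicted class-1 probabilities
#'
#' Runs the model in inference mode (running batch-norm statistics, no
#' dropout), in memory-bounded chunks.
#'
#' @param model a trained model.
#' @param x an n x p x C array, [omics_tensor()], or (for MLP-compatible
#'   shapes) an n x (p*C) matrix.
#' @param chunk rows per forward pass, default 1024 (bounds the memory used
#'   by the convolution design matrices).
#' @return numeric vector of class-1 probabilities.
#' @export
predict_proba <- function(model, x, chunk = 1024L) {
  if (inherits(x, "omics_tensor")) x <- x$x
  if (length(dim(x)) == 2) {
    nc <- if (model$kind == "mlp") model$n_features else
      model$n_channels * length(model$hierarchy$node_ids)
    p <- nc / (if (model$kind == "mlp") 1 else model$n_channels)
    if (model$kind != "mlp")
      x <- array(x, c(nrow(x), p, model$n_channels))
    else x <- array(x, c(nrow(x), ncol(x), 1))
  }
  if (model$kind == "gcn") x <- pad_signal(x, model$hierarchy)
  n <- dim(x)[1]
  out <- numeric(n)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    fwd <- gcn_forward(model, model$params, model$state,
                       x[s:e, , , drop = FALSE], training = FALSE)
    out[s:e] <- softmax_probs(fwd$logits)[, 2]
  }
  out
}

#' Confusion-count classification metrics
#'
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)` and
#' `F1 = 2 TP / (2 TP + FP + FN)` (0 when the denominator is 0).
#'
#' @param tp,tn,fp,fn confusion counts.
#' @return object of class `classification_metrics`.
#' @export
metrics_from_counts <- function(tp, tn, fp, fn) {
  total <- tp + tn + fp + fn
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn,
                 accuracy = (tp + tn) / total,
                 f1 = if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)),
            class = "classification_metrics")
}

#' Evaluate a trained model on held-out samples
#'
#' @param model trained model.
#' @param tensor the (standardized) [omics_tensor()].
#' @param idx row indices to score.
#' @return `classification_metrics` with predictions attached.
#' @export
evaluate_model <- function(model, tensor, idx) {
  prob <- predict_proba(model, tensor$x[idx, , , drop = FALSE])
  pred <- as.integer(prob > 0.5)
  y <- tensor$labels[idx]
  m <- metrics_from_counts(sum(pred == 1 & y == 1), sum(pred == 0 & y == 0),
                           sum(pred == 1 & y == 0), sum(pred == 0 & y == 1))
  m$predictions <- pred
  m$probabilities <- prob
  m
}

#' Cross-validated training and test evaluation of the graph model
#'
#' Implements the evaluation protocol: hold out a stratified 20% test set,
#' split the remainder into `folds` stratified folds, train one model per
#' fold (that fold as validation, the rest as training), and score every
#' model on the fixed test set. Standardization statistics are recomputed
#' from each model's training rows only.
#'
#' @param tensor a raw (unstandardized) [omics_tensor()].
#' @param graph the [weighted_graph()] carrying the node structure.
#' @param config a [model_config()].
#' @param plan optional pre-built [make_split_plan()]; defaults to one seeded
#'   from the config.
#' @param keep_models keep the trained fold models (default TRUE).
#' @return object of class `cv_result`: `fold_metrics` (data frame),
#'   `mean_accuracy`, `se_accuracy`, `mean_f1`, `se_f1`, `models`, `plan`,
#'   `hierarchy`.
#' @export
cross_validate <- function(tensor, graph, config = model_config(),
                           plan = NULL, keep_models = TRUE) {
  hierarchy <- graclus_coarsen(graph, levels = length(config$conv_filters),
                               seed = config$seed,
                               pool_size = config$pool[1])
  if (is.null(plan))
    plan <- make_split_plan(tensor$labels, seed = config$seed,
                            folds = config$folds)
  folds <- plan$folds
  if (folds < 2) stop("standard error undefined for a single fold")
  fold_metrics <- NULL
  models <- list()
  C <- dim(tensor$x)[3]
  for (f in seq_len(folds)) {
    tr <- which(plan$fold != f & !is.na(plan$fold))
    va <- which(plan$fold == f)
    std <- standardize_omics(tensor, tr)
    cfg <- config
    cfg$seed <- config$seed + 1000L * f
    model <- build_model(cfg, hierarchy, C)
    model <- train_model(model, std, tr, va)
    model$scaler <- std$scaler
    m <- evaluate_model(model, std, plan$test)
    fold_metrics <- rbind(fold_metrics,
                          data.frame(fold = f, accuracy = m$accuracy,
                                     f1 = m$f1, TP = m$TP, TN = m$TN,
                                     FP = m$FP, FN = m$FN))
    if (keep_models) models[[f]] <- model
  }
  se <- function(v) stats::sd(v) / sqrt(length(v))
  structure(list(fold_metrics = fold_metrics,
                 mean_accuracy = mean(fold_metrics$accuracy),
                 se_accuracy = se(fold_metrics$accuracy),
                 mean_f1 = mean(fold_metrics$f1),
                 se_f1 = se(fold_metrics$f1),
                 models = models, plan = plan, hierarchy = hierarchy,
                 config = config),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: accuracy %.4f +/- %.4f, F1 %.4f +/- %.4f (%d folds)\n",
              x$mean_accuracy, x$se_accuracy, x$mean_f1, x$se_f1,
              nrow(x$fold_metrics)))
  invisible(x)
}

#' Paired t-test between two models' fold accuracies
#'
#' Two-sided paired Student t-test on fold-wise accuracy differences. A
#' zero-variance difference vector is flagged degenerate: p = 1 when the mean
#' difference is 0, NA otherwise.
#'
#' @param metrics_a,metrics_b equal-length numeric vectors of per-fold
#'   accuracies, or `cv_result` objects.
#' @return list with `t`, `p`, `mean_diff`, `degenerate`.
#' @export
compare_models <- function(metrics_a, metrics_b) {
  va <- if (inherits(metrics_a, "cv_result")) metrics_a$fold_metrics$accuracy else metrics_a
  vb <- if (inherits(metrics_b, "cv_result")) metrics_b$fold_metrics$accuracy else metrics_b
  if (length(va) != length(vb)) stop("paired vectors must have equal length")
  d <- va - vb
  if (stats::sd(d) < 1e-12) {
    return(list(t = if (mean(d) == 0) 0 else NA_real_,
                p = if (mean(d) == 0) 1 else NA_real_,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(va, vb, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, mean_diff = mean(d),
       degenerate = FALSE)
}

# train/tune/evaluate the MLP baseline for one fold
mlp_fold <- function(tensor, tr, va, test, config, l2_grid) {
  std <- standardize_omics(tensor, tr)
  best <- NULL; best_acc <- -Inf
  for (l2 in l2_grid) {
    cfg <- config
    cfg$l2 <- l2
    m <- build_mlp(cfg, prod(dim(std$x)[-1]))
    m <- train_model(m, std, tr, va)
    va_acc <- evaluate_model(m, std, va)$accuracy
    if (va_acc > best_acc) { best_acc <- va_acc; best <- m }
  }
  evaluate_model(best, std, test)
}

#' Reference (non-graph) classifiers on flattened features
#'
#' Fits the conventional baselines on the flattened `n x (p*C)` feature
#' matrix using exactly the same split plan as the graph model, tuning a
#' small grid on each validation fold. The MLP is built in; random forest,
#' SVM and gradient boosting require the optional packages `randomForest`,
#' `e1071`, `xgboost` and are skipped with a warning when unavailable.
#'
#' @param tensor raw [omics_tensor()].
#' @param plan a [make_split_plan()] shared with the graph model.
#' @param config a [model_config()] (optimizer settings reused by the MLP).
#' @param baselines subset of `c("mlp", "rf", "svm", "xgb")`.
#' @return named list of per-baseline results, each with `fold_metrics`,
#'   `mean_accuracy`, `se_accuracy`, `mean_f1`, `se_f1`.
#' @export
run_baselines <- function(tensor, plan, config = model_config(),
                          baselines = c("mlp", "rf", "svm", "xgb")) {
  flat_raw <- flatten_tensor(tensor)
  y <- tensor$labels
  test <- plan$test
  se <- function(v) stats::sd(v) / sqrt(length(v))
  out <- list()
  summarize <- function(rows) {
    list(fold_metrics = rows, mean_accuracy = mean(rows$accuracy),
         se_accuracy = se(rows$accuracy), mean_f1 = mean(rows$f1),
         se_f1 = se(rows$f1))
  }
  fold_sets <- lapply(seq_len(plan$folds), function(f)
    list(tr = which(plan$fold != f & !is.na(plan$fold)),
         va = which(plan$fold == f)))
  for (bl in baselines) {
    if (bl != "mlp") {
      pkg <- c(rf = "randomForest", svm = "e1071", xgb = "xgboost")[[bl]]
      if (!requireNamespace(pkg, quietly = TRUE)) {
        warning(sprintf("baseline '%s' skipped: package '%s' not installed",
                        bl, pkg))
        next
      }
    }
    rows <- NULL
    for (f in seq_along(fold_sets)) {
      tr <- fold_sets[[f]]$tr; va <- fold_sets[[f]]$va
      m <- if (bl == "mlp") {
        cfg <- config
        cfg$seed <- config$seed + 1000L * f
        mlp_fold(tensor, tr, va, test, cfg, l2_grid = c(config$l2, 10 * config$l2))
      } else {
        mu <- colMeans(flat_raw[tr, , drop = FALSE])
        sdv <- apply(flat_raw[tr, , drop = FALSE], 2, stats::sd)
        sdv[sdv < 1e-12] <- 1
        flat <- sweep(sweep(flat_raw, 2, mu), 2, sdv, "/")
        fit_classic_baseline(bl, flat, y, tr, va, test,
                             seed = config$seed + 1000L * f)
      }
      rows <- rbind(rows, data.frame(fold = f, accuracy = m$accuracy,
                                     f1 = m$f1))
    }
    out[[bl]] <- summarize(rows)
  }
  out
}

# small tuned grids for the optional classical baselines
fit_classic_baseline <- function(kind, flat, y, tr, va, test, seed) {
  predict_counts <- function(pred) {
    metrics_from_counts(sum(pred == 1 & y[test] == 1),
                        sum(pred == 0 & y[test] == 0),
                        sum(pred == 1 & y[test] == 0),
                        sum(pred == 0 & y[test] == 1))
  }
  with_seed(seed, {
    if (kind == "rf") {
      grid <- c(floor(sqrt(ncol(flat))), max(2, floor(ncol(flat) / 4)))
      fits <- lapply(grid, function(mtry)
        randomForest::randomForest(flat[tr, ], factor(y[tr]), mtry = mtry,
                                   ntree = 500))
      acc <- vapply(fits, function(f)
        mean(stats::predict(f, flat[va, ]) == factor(y[va])), numeric(1))
      best <- fits[[which.max(acc)]]
      predict_counts(as.integer(as.character(stats::predict(best, flat[test, ]))))
    } else if (kind == "svm") {
      fits <- lapply(c(1, 10), function(cost)
        e1071::svm(flat[tr, ], factor(y[tr]), kernel = "radial", cost = cost))
      acc <- vapply(fits, function(f)
        mean(stats::predict(f, flat[va, ]) == factor(y[va])), numeric(1))
      best <- fits[[which.max(acc)]]
      predict_counts(as.integer(as.character(stats::predict(best, flat[test, ]))))
    } else {
      fits <- lapply(c(3, 6), function(depth)
        xgboost::xgboost(data = flat[tr, ], label = y[tr], max_depth = depth,
                         eta = 0.1, nrounds = 100, objective = "binary:logistic",
                         verbose = 0))
      acc <- vapply(fits, function(f)
        mean(as.integer(stats::predict(f, flat[va, ]) > 0.5) == y[va]),
        numeric(1))
      best <- fits[[which.max(acc)]]
      predict_counts(as.integer(stats::predict(best, flat[test, ]) > 0.5))
    }
  })
}
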