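# Internal neural-network primitives: plain matrices, hand-written backprop.
# All layers operate on 2-D matrices; graph-conv code reshapes around them.
# No deep-learning framework is available in this stack, and the training
# loop is small enough that BLAS-backed base R is adequate on CPU.

# column-broadcast helpers: much faster than sweep() (no aperm/array copies)
.csub <- function(x, v) x - rep(v, each = nrow(x))
.cmul <- function(x, v) x * rep(v, each = nrow(x))
.cadd <- function(x, v) x + rep(v, each = nrow(x))

# batch normalization (population variance over the batch, running stats with
# momentum 0.9 for inference); the fused kernels live in src/nn_kernels.cpp
bn_forward <- function(x, gamma, beta, training, run_mean, run_var,
                       momentum = 0.9, eps = 1e-5) {
  out <- bn_forward_cpp(x, as.numeric(gamma), as.numeric(beta), training,
                        as.numeric(run_mean), as.numeric(run_var),
                        momentum, eps)
  list(y = out$y,
       cache = list(xc = out$xc, ivar = as.numeric(out$ivar),
                    gamma = as.numeric(gamma)),
       run_mean = as.numeric(out$run_mean), run_var = as.numeric(out$run_var))
}

bn_backward <- function(dy, cache) {
  out <- bn_backward_cpp(dy, cache$xc, cache$ivar, cache$gamma)
  list(dx = out$dx, dgamma = as.numeric(out$dgamma),
       dbeta = as.numeric(out$dbeta))
}

relu_forward <- function(x) list(y = relu_cpp(x))

dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- matrix(stats::runif(length(x)) >= rate, nrow(x), ncol(x)) / (1 - rate)
  list(y = x * mask, mask = mask)
}

fc_forward <- function(x, W, b) {
  list(y = .cadd(x %*% W, b), x = x)
}

fc_backward <- function(dy, cache, W) {
  list(dx = dy %*% t(W), dW = crossprod(cache$x, dy), db = colSums(dy))
}

softmax_probs <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# cross-entropy on two classes; y in {0,1}; returns loss and dlogits
softmax_ce <- function(logits, y) {
  probs <- softmax_probs(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(probs[idx], 1e-12)))
  dlogits <- probs
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n, probs = probs)
}

# --- Chebyshev graph convolution as a trainable layer ------------------------

# forward: X array n x p x C_in -> Y n x p x C_out, caching the basis stack;
# Chebyshev signals are written straight into the (n*p) x (K*C_in) design
# matrix so one GEMM produces all output channels.
cheb_conv_forward <- function(X, scaled_L, theta, bias) {
  dims <- dim(X)
  n <- dims[1]; p <- dims[2]; C_in <- dims[3]
  K <- dim(theta)[1]; C_out <- dim(theta)[3]
  Zmat <- matrix(0, n * p, K * C_in)
  for (c in seq_len(C_in)) {
    off <- (c - 1) * K
    T0 <- matrix(X[, , c], n, p)
    Zmat[, off + 1] <- T0
    if (K >= 2) {
      T1 <- as.matrix(T0 %*% scaled_L)
      Zmat[, off + 2] <- T1
      if (K >= 3) for (k in 3:K) {
        T2 <- 2 * as.matrix(T1 %*% scaled_L) - T0
        Zmat[, off + k] <- T2
        T0 <- T1; T1 <- T2
      }
    }
  }
  Th <- matrix(theta, K * C_in, C_out)
  Y <- array(Zmat %*% Th, c(n, p, C_out))
  if (any(bias != 0)) Y <- Y + rep(bias, each = n * p)
  list(y = Y, Zmat = Zmat, dims = dims, K = K)
}

# Clenshaw accumulation of sum_k T_{k-1}(L) C_k for matrix "coefficients"
cheb_adjoint <- function(Clist, scaled_L) {
  K <- length(Clist)
  if (K == 1) return(Clist[[1]])
  b1 <- Clist[[K]]
  b2 <- NULL
  if (K >= 3) for (k in seq(K - 1, 2)) {
    bnew <- Clist[[k]] + 2 * as.matrix(b1 %*% scaled_L) - (if (is.null(b2)) 0 else b2)
    b2 <- b1; b1 <- bnew
  }
  Clist[[1]] + as.matrix(b1 %*% scaled_L) - (if (is.null(b2)) 0 else b2)
}

cheb_conv_backward <- function(dY, cache, scaled_L, theta) {
  n <- cache$dims[1]; p <- cache$dims[2]; C_in <- cache$dims[3]
  K <- cache$K; C_out <- dim(theta)[3]
  dYmat <- matrix(dY, n * p, C_out)
  Th <- matrix(theta, K * C_in, C_out)
  dTheta <- array(crossprod(cache$Zmat, dYmat), dim(theta))
  dbias <- colSums(dYmat)
  dZmat <- dYmat %*% t(Th)
  dX <- array(0, cache$dims)
  for (c in seq_len(C_in)) {
    block <- dZmat[, ((c - 1) * K + 1):(c * K), drop = FALSE]
    Clist <- lapply(seq_len(K), function(k) matrix(block[, k], n, p))
    dX[, , c] <- cheb_adjoint(Clist, scaled_L)
  }
  list(dx = dX, dtheta = dTheta, dbias = dbias)
}

# --- Adam optimizer over a named list of arrays ------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# accumulate gradient arrays g into named list acc
grad_acc <- function(acc, nm, g) {
  acc[[nm]] <- if (is.null(acc[[nm]])) g else acc[[nm]] + g
  acc
}
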