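# Independent oracles used to cross-check the implementation. Each one uses a
# different algorithm (or brute force) from the production code path.

# ADMM solver for the weighted graphical lasso (penalty matrix P, diagonal
# unpenalized). Production code uses block coordinate descent; agreement is a
# genuine dual-route check.
admm_glasso <- function(S, P, rho = 1, iters = 5000, tol = 1e-11) {
  p <- nrow(S)
  Theta <- diag(1 / diag(S))
  Z <- Theta
  U <- matrix(0, p, p)
  for (it in seq_len(iters)) {
    eig <- eigen(rho * (Z - U) - S, symmetric = TRUE)
    d <- (eig$values + sqrt(eig$values^2 + 4 * rho)) / (2 * rho)
    Theta <- eig$vectors %*% (d * t(eig$vectors))
    Zold <- Z
    M <- Theta + U
    Z <- sign(M) * pmax(abs(M) - P / rho, 0)
    diag(Z) <- diag(M)
    U <- U + Theta - Z
    if (max(abs(Z - Zold)) < tol && max(abs(Theta - Z)) < tol) break
  }
  (Z + t(Z)) / 2
}

# dense spectral filtering oracle: U g(Lambda~) U' x via full eigendecomposition
dense_cheb_oracle <- function(X, L, lambda_max, theta_vec) {
  e <- eigen(as.matrix(L), symmetric = TRUE)
  tau_hat <- 2 * e$values / lambda_max - 1
  K <- length(theta_vec)
  g <- as.numeric(chebyshev_polynomials(tau_hat, K) %*% theta_vec)
  as.matrix(X) %*% t(e$vectors %*% (g * t(e$vectors)))
}

# traversal-based connected-component counter (no linear algebra)
count_components <- function(adj) {
  p <- nrow(adj)
  seen <- logical(p)
  n <- 0L
  for (s in seq_len(p)) {
    if (seen[s]) next
    n <- n + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[v, ] != 0 & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  n
}

# brute-force hypergeometric tail: enumerate all size-n draws from N items
brute_hyper_tail <- function(N, K, n, sig) {
  draws <- utils::combn(N, n)
  in_term <- seq_len(K)           # first K items are the term members
  hits <- colSums(matrix(draws %in% in_term, nrow = n))
  mean(hits >= sig)
}

# random small weighted graph for property checks
random_graph <- function(p, edge_prob = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(0, p, p)
  up <- which(upper.tri(A))
  on <- up[runif(length(up)) < edge_prob]
  A[on] <- runif(length(on), 0.2, 1)
  A <- A + t(A)
  weighted_graph(sprintf("v%02d", seq_len(p)), A)
}

# tiny two-channel synthetic dataset for model tests
tiny_dataset <- function(p = 16, n = 48, seed = 9, delta = 1.5) {
  sp <- synth_spec(p = p, n = n, graph_model = "er", avg_degree = 3,
                   signal_size = 4, delta = delta, rho = 0.5, seed = seed)
  gg <- generate_graph(sp)
  generate_omics(gg, sp)
}
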