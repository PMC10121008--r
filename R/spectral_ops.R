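#' Eigendecomposition of a graph Laplacian (graph Fourier basis)
#'
#' Returns the orthonormal eigenvectors U and ascending eigenvalues of L.
#' Used for analysis and as the dense oracle in tests; production filtering
#' never forms this decomposition.
#'
#' @param laplacian a `laplacian_matrix` from [build_laplacian()].
#' @return list of class `spectral_basis` with `U` (p x p, columns are
#'   eigenvectors) and `tau` (ascending eigenvalues).
#' @export
spectral_basis <- function(laplacian) {
  e <- eigen(as.matrix(laplacian$matrix), symmetric = TRUE)
  o <- order(e$values)
  structure(list(U = e$vectors[, o, drop = FALSE], tau = e$values[o]),
            class = "spectral_basis")
}

#' Graph Fourier transform and its inverse
#'
#' The forward transform projects a node signal onto the Laplacian
#' eigenvectors, `xhat = t(U) %*% x`; the inverse reconstructs `x = U %*% xhat`.
#'
#' @param x length-p signal (or p x m matrix of signals in columns).
#' @param basis a [spectral_basis()].
#' @return spectral coefficients (forward) or node signal (inverse), same
#'   shape as the input.
#' @export
graph_fourier <- function(x, basis) {
  x <- as.matrix(x)
  if (nrow(x) != nrow(basis$U)) stop("signal length does not match basis")
  drop(crossprod(basis$U, x))
}

#' @rdname graph_fourier
#' @param xhat spectral coefficients.
#' @export
inverse_graph_fourier <- function(xhat, basis) {
  xhat <- as.matrix(xhat)
  if (nrow(xhat) != ncol(basis$U)) stop("coefficient length does not match basis")
  drop(basis$U %*% xhat)
}

#' Rescale a Laplacian so its spectrum lies in \[-1, 1\]
#'
#' Chebyshev polynomials are defined on \[-1, 1\]; the affine map
#' `2 L / lambda_max - I` sends eigenvalue 0 to -1 and lambda_max to +1.
#'
#' @param L sparse symmetric Laplacian matrix (or `laplacian_matrix`).
#' @param lambda_max positive largest-eigenvalue estimate; taken from the
#'   object when `L` is a `laplacian_matrix` and `lambda_max` is missing.
#' @return sparse scaled operator.
#' @export
scale_laplacian <- function(L, lambda_max = NULL) {
  if (inherits(L, "laplacian_matrix")) {
    if (is.null(lambda_max)) lambda_max <- L$lambda_max
    L <- L$matrix
  }
  if (is.null(lambda_max) || lambda_max <= 0) stop("lambda_max must be positive")
  methods::as(methods::as(2 * L / lambda_max - Matrix::Diagonal(nrow(L)),
                          "generalMatrix"), "CsparseMatrix")
}

#' Chebyshev polynomials of the first kind, by the stable recurrence
#'
#' T_0 = 1, T_1 = x, T_k = 2 x T_{k-1} - T_{k-2}. Returns the first K
#' polynomials evaluated at `x` (scalar or vector).
#'
#' @param x evaluation points.
#' @param K number of polynomials (order K - 1 highest), K >= 1.
#' @return length(x) x K matrix with column k holding T_{k-1}(x).
#' @export
chebyshev_polynomials <- function(x, K) {
  if (K < 1) stop("K must be >= 1")
  x <- as.numeric(x)
  out <- matrix(0, length(x), K)
  out[, 1] <- 1
  if (K >= 2) out[, 2] <- x
  if (K >= 3) for (k in 3:K) out[, k] <- 2 * x * out[, k - 1] - out[, k - 2]
  out
}

#' Bank of Chebyshev graph-filter coefficients
#'
#' Holds the learnable coefficients of one graph-convolution layer:
#' `theta[k, c_in, c_out]` weights the k-th Chebyshev term mapping input
#' channel `c_in` to output channel `c_out`, plus one additive bias per
#' output channel.
#'
#' @param theta numeric array K x C_in x C_out (a matrix is promoted to
#'   K x 1 x 1 column-wise when C_in = C_out = 1).
#' @param bias optional numeric length C_out, default zeros.
#' @return object of class `cheb_filter_bank`.
#' @export
cheb_filter_bank <- function(theta, bias = NULL) {
  if (is.null(dim(theta))) theta <- array(theta, c(length(theta), 1, 1))
  if (length(dim(theta)) != 3) stop("theta must be a K x C_in x C_out array")
  if (!all(is.finite(theta))) stop("theta must be finite")
  K <- dim(theta)[1]
  if (K < 1) stop("filter order K must be >= 1")
  if (is.null(bias)) bias <- numeric(dim(theta)[3])
  stopifnot(length(bias) == dim(theta)[3])
  structure(list(theta = theta, bias = bias, K = K), class = "cheb_filter_bank")
}

# Stack of Chebyshev basis signals for a batch: input X (n x p), returns
# n x p x K array with slice k = X %*% T_{k-1}(Lhat)  (Lhat symmetric, so
# right-multiplication applies the operator to each row signal).
cheb_basis_stack <- function(X, scaled_L, K) {
  n <- nrow(X); p <- ncol(X)
  Z <- array(0, c(n, p, K))
  T0 <- X
  Z[, , 1] <- T0
  if (K >= 2) {
    T1 <- as.matrix(X %*% scaled_L)
    Z[, , 2] <- T1
    if (K >= 3) for (k in 3:K) {
      T2 <- 2 * as.matrix(T1 %*% scaled_L) - T0
      Z[, , k] <- T2
      T0 <- T1; T1 <- T2
    }
  }
  Z
}

#' Chebyshev graph filtering of multi-channel node signals
#'
#' Applies `sum_k theta_k T_k(Lhat) x` per input channel, summed over input
#' channels for each output channel, using only the sparse three-term
#' recurrence: the dense polynomial of the Laplacian is never formed, so the
#' cost is O(K |E|) per signal.
#'
#' @param X n x p matrix (single channel) or n x p x C_in array of node
#'   signals aligned to the graph behind `scaled_L`.
#' @param scaled_L sparse rescaled Laplacian from [scale_laplacian()].
#' @param bank a [cheb_filter_bank()] with matching C_in.
#' @return n x p x C_out array of filtered feature maps.
#' @export
cheb_filter <- function(X, scaled_L, bank) {
  if (length(dim(X)) == 2 || is.null(dim(X))) {
    X <- array(as.matrix(X), c(NROW(as.matrix(X)), NCOL(as.matrix(X)), 1))
  }
  dims <- dim(X)
  n <- dims[1]; p <- dims[2]; C_in <- dims[3]
  K <- dim(bank$theta)[1]
  if (dim(bank$theta)[2] != C_in)
    stop(sprintf("filter bank expects %d input channels, got %d",
                 dim(bank$theta)[2], C_in))
  if (p != nrow(scaled_L)) stop("signal length does not match graph size")
  C_out <- dim(bank$theta)[3]
  # Zmat: (n*p) x (K*C_in), columns ordered k fastest within channel
  Zmat <- matrix(0, n * p, K * C_in)
  for (c in seq_len(C_in)) {
    Zc <- cheb_basis_stack(matrix(X[, , c], n, p), scaled_L, K)
    Zmat[, ((c - 1) * K + 1):(c * K)] <- matrix(Zc, n * p, K)
  }
  Th <- matrix(aperm(bank$theta, c(1, 2, 3)), K * C_in, C_out)
  Y <- Zmat %*% Th
  Y <- array(Y, c(n, p, C_out))
  if (any(bank$bias != 0))
    Y <- sweep(Y, 3, bank$bias, "+")
  Y
}
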