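#' Log-spaced regularization path for sparse network estimation
#'
#' Builds the penalty grid used for network refinement: `count` values
#' log-equally spaced between `min_ratio * lambda_max_reg` and
#' `lambda_max_reg` (defaults: 40 values spanning two decades).
#'
#' @param lambda_max_reg upper end of the path (the smallest penalty that
#'   fully sparsifies the off-diagonal; see [compute_lambda_max()]).
#' @param min_ratio lower end as a fraction of `lambda_max_reg`, default 0.01.
#' @param count number of grid values, default 40.
#' @return object of class `lambda_path` with ascending `values`.
#' @export
make_lambda_path <- function(lambda_max_reg, min_ratio = 0.01, count = 40L) {
  if (lambda_max_reg <= 0) stop("lambda_max_reg must be positive")
  if (min_ratio <= 0 || min_ratio >= 1) stop("min_ratio must be in (0,1)")
  if (count < 2) stop("count must be >= 2")
  values <- exp(seq(log(min_ratio * lambda_max_reg), log(lambda_max_reg),
                    length.out = count))
  values[1] <- min_ratio * lambda_max_reg
  values[count] <- lambda_max_reg
  structure(list(lambda_max_reg = lambda_max_reg, min_ratio = min_ratio,
                 values = values), class = "lambda_path")
}

#' Smallest penalty giving a fully diagonal graphical-lasso solution
#'
#' For the L1-penalized Gaussian likelihood this is the maximum absolute
#' off-diagonal entry of the sample covariance: at or above it, every
#' off-diagonal of the estimated precision is shrunk to zero.
#'
#' @param sample_cov symmetric sample covariance, p >= 2.
#' @return a nonnegative scalar.
#' @export
compute_lambda_max <- function(sample_cov) {
  p <- nrow(sample_cov)
  if (is.null(p) || p < 2) stop("need at least a 2 x 2 covariance")
  off <- abs(sample_cov)
  diag(off) <- 0
  max(off)
}

#' Prior-weighted sparse inverse-covariance estimation
#'
#' Solves the L1-penalized Gaussian log-likelihood
#' `max log det(Theta) - tr(S Theta) - sum_ij lambda W_ij |Theta_ij|`
#' where the penalty weight `W_ij` is `prior_factor` for node pairs connected
#' in the prior network, 1 for all other pairs, and 0 on the diagonal, so
#' prior edges are penalized less and survive more easily. With
#' `prior_factor = 1` (or a `NULL` prior) this is the standard graphical
#' lasso. The solver is block coordinate descent with lasso subproblems
#' (compiled); a non-positive-definite intermediate triggers one retry with a
#' 1e-6 diagonal jitter.
#'
#' @param sample_cov symmetric positive-semidefinite p x p covariance.
#' @param prior_graph a [weighted_graph()] on the same node order, or `NULL`.
#' @param lambda penalty level (> 0 unless the covariance is diagonal).
#' @param prior_factor penalty multiplier on prior edges, default 0.1.
#' @param tol convergence threshold on the maximum parameter change between
#'   full sweeps, default 1e-4.
#' @param max_sweeps sweep cap, default 200.
#' @param n_obs optional sample count behind `sample_cov`; scales the
#'   reported log-likelihood (per-observation if omitted).
#' @param warm_start optional fit returned previously on the same problem
#'   shape (used internally for path fits).
#' @return object of class `precision_estimate`: `theta` (symmetric positive
#'   definite), `edge_set` (two-column matrix of off-diagonal support above
#'   1e-8), `lambda`, `loglik`, `sweeps`, `converged`.
#' @export
fit_prior_glasso <- function(sample_cov, prior_graph = NULL, lambda,
                             prior_factor = 0.1, tol = 1e-4,
                             max_sweeps = 200L, n_obs = NULL,
                             warm_start = NULL) {
  S <- as.matrix(sample_cov)
  p <- nrow(S)
  if (max(abs(S - t(S))) > 1e-8) stop("sample covariance must be symmetric")
  if (lambda < 0) stop("lambda must be nonnegative")
  W <- matrix(1, p, p)
  if (!is.null(prior_graph)) {
    if (length(prior_graph$node_ids) != p)
      stop("prior graph order does not match covariance")
    W[as.matrix(prior_graph$adjacency) != 0] <- prior_factor
  }
  P <- lambda * W
  diag(P) <- 0
  warm <- !is.null(warm_start)
  W0 <- if (warm) warm_start$.w else matrix(0, p, p)
  B0 <- if (warm) warm_start$.b else matrix(0, p, p)
  run <- function(Smat) glasso_weighted_cpp(Smat, P, tol, as.integer(max_sweeps),
                                            tol * 0.1, 1000L, W0, B0, warm)
  fit <- tryCatch(run(S), error = function(e) NULL)
  if (is.null(fit) || inherits(tryCatch(chol(fit$theta), error = identity),
                               "error")) {
    fit <- run(S + diag(1e-6, p))   # jittered retry
    if (inherits(tryCatch(chol(fit$theta), error = identity), "error"))
      stop("graphical lasso failed: non-positive-definite solution")
  }
  theta <- fit$theta
  supp <- which(abs(theta) > 1e-8 & row(theta) < col(theta), arr.ind = TRUE)
  nobs <- if (is.null(n_obs)) 1 else n_obs
  ll <- nobs / 2 * (determinant(theta, logarithm = TRUE)$modulus[1] -
                      sum(S * theta) - p * log(2 * pi))
  structure(list(theta = theta, edge_set = supp, lambda = lambda,
                 loglik = as.numeric(ll), sweeps = fit$sweeps,
                 converged = fit$converged, .w = fit$w, .b = fit$b),
            class = "precision_estimate")
}

#' Penalty selection by fold-wise held-out BIC and the one-SE rule
#'
#' For each candidate penalty, the model is fit on each fold's complement and
#' scored on the held-out fold:
#' `BIC = -2 * heldout_loglik + log(n_fold) * k`, with `k` the number of
#' nonzero off-diagonal pairs (each symmetric pair counted once) and `n_fold`
#' the held-out sample count. The mean BIC across folds and its standard
#' error give the selection: `"min"` picks the minimizer; `"one_se"`
#' (default) picks the largest (sparsest) penalty whose mean BIC is within
#' one standard error of the minimum.
#'
#' @param sample_data n x p data matrix (rows = samples).
#' @param prior_graph prior network or `NULL` (see [fit_prior_glasso()]).
#' @param path a [make_lambda_path()] object (or numeric vector of penalties).
#' @param folds number of cross-validation folds, default 4.
#' @param rule `"one_se"` or `"min"`.
#' @param prior_factor passed to [fit_prior_glasso()].
#' @param seed seed for the fold assignment.
#' @param ... further arguments to [fit_prior_glasso()].
#' @return object of class `selection_result`: `chosen_lambda`, `rule`, and a
#'   `table` data frame (lambda, mean BIC, SE, mean edge count).
#' @export
select_lambda <- function(sample_data, prior_graph = NULL, path,
                          folds = 4L, rule = c("one_se", "min"),
                          prior_factor = 0.1, seed = 1L, ...) {
  rule <- match.arg(rule)
  lambdas <- if (inherits(path, "lambda_path")) path$values else sort(path)
  X <- as.matrix(sample_data)
  n <- nrow(X); p <- ncol(X)
  if (n < folds * 2) stop("need at least 2 samples per fold")
  assign_f <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  nl <- length(lambdas)
  bic <- matrix(NA_real_, folds, nl)
  k_count <- matrix(NA_real_, folds, nl)
  failed <- character(0)
  for (f in seq_len(folds)) {
    tr <- X[assign_f != f, , drop = FALSE]
    ho <- X[assign_f == f, , drop = FALSE]
    mu <- colMeans(tr)
    S_tr <- stats::cov(tr)
    ho_c <- sweep(ho, 2, mu)
    S_ho <- crossprod(ho_c) / nrow(ho_c)
    warm <- NULL
    for (li in rev(seq_len(nl))) {       # descending lambda, warm-started
      fit <- tryCatch(
        fit_prior_glasso(S_tr, prior_graph, lambdas[li],
                         prior_factor = prior_factor, warm_start = warm, ...),
        error = function(e) NULL)
      if (is.null(fit)) { failed <- c(failed, sprintf("fold %d lambda %.4g", f, lambdas[li])); next }
      warm <- fit
      k <- nrow(fit$edge_set)
      n_ho <- nrow(ho_c)
      ll <- n_ho / 2 * (determinant(fit$theta, logarithm = TRUE)$modulus[1] -
                          sum(S_ho * fit$theta) - p * log(2 * pi))
      bic[f, li] <- -2 * as.numeric(ll) + log(n_ho) * k
      k_count[f, li] <- k
    }
  }
  if (all(is.na(bic)))
    stop(paste("all penalized fits diverged:", paste(failed, collapse = "; ")))
  mean_bic <- colMeans(bic)
  se_bic <- apply(bic, 2, stats::sd) / sqrt(folds)
  chosen <- one_se_choice(lambdas, mean_bic, se_bic, rule)
  structure(list(chosen_lambda = chosen, rule = rule,
                 table = data.frame(lambda = lambdas, mean_bic = mean_bic,
                                    se_bic = se_bic,
                                    mean_edges = colMeans(k_count)),
                 failed = failed),
            class = "selection_result")
}

# selection rule on a computed criterion curve: "min" takes the minimizer,
# "one_se" the largest (sparsest) penalty within one SE of the minimum
one_se_choice <- function(lambdas, mean_crit, se_crit, rule = "one_se") {
  ok <- is.finite(mean_crit)
  jmin <- which(ok)[which.min(mean_crit[ok])]
  if (rule == "min") return(lambdas[jmin])
  thr <- mean_crit[jmin] + se_crit[jmin]
  max(lambdas[ok & mean_crit <= thr])
}

#' Refine a prior network from expression data
#'
#' Convenience wrapper running the full refinement protocol: compute the
#' penalty upper bound from the sample covariance, build the 40-value
#' log-spaced path, select a penalty by fold-wise BIC with the one-SE rule,
#' and fit the final prior-weighted model on all samples. The returned graph
#' carries absolute partial-correlation edge weights.
#'
#' @inheritParams select_lambda
#' @param count path length, default 40.
#' @param min_ratio path lower fraction, default 0.01.
#' @return list with `graph` (refined [weighted_graph()]), `fit`
#'   (`precision_estimate`), `selection` (`selection_result`), `path`.
#' @export
refine_network <- function(sample_data, prior_graph, folds = 4L,
                           prior_factor = 0.1, min_ratio = 0.01, count = 40L,
                           seed = 1L, ...) {
  X <- as.matrix(sample_data)
  S <- stats::cov(X)
  lmax <- compute_lambda_max(S)
  path <- make_lambda_path(lmax, min_ratio = min_ratio, count = count)
  sel <- select_lambda(X, prior_graph, path, folds = folds,
                       prior_factor = prior_factor, seed = seed, ...)
  fit <- fit_prior_glasso(S, prior_graph, sel$chosen_lambda,
                          prior_factor = prior_factor, n_obs = nrow(X), ...)
  p <- ncol(X)
  ids <- if (!is.null(prior_graph)) prior_graph$node_ids else
    colnames(X) %||% sprintf("n%0*d", nchar(p), seq_len(p))
  adj <- precision_to_adjacency(fit$theta)
  dimnames(adj) <- list(ids, ids)
  list(graph = weighted_graph(ids, adj, sort_nodes = FALSE),
       fit = fit, selection = sel, path = path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Partial-correlation magnitude adjacency from a precision matrix.
precision_to_adjacency <- function(theta) {
  d <- sqrt(diag(theta))
  pc <- -theta / tcrossprod(d)
  diag(pc) <- 0
  pc[abs(pc) <= 1e-8] <- 0
  Matrix::drop0(Matrix::Matrix(abs(pc), sparse = TRUE))
}

#' Write a penalty-selection report as TSV
#' @param selection a `selection_result`.
#' @param path output file.
#' @export
write_selection_report <- function(selection, path) {
  utils::write.table(selection$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
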