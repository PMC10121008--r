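chain_data <- function(p = 20, n = 1000, seed = 7, rho = 0.4) {
  Th <- diag(1.2, p)
  for (i in 1:(p - 1)) Th[i, i + 1] <- Th[i + 1, i] <- rho
  set.seed(seed)
  X <- t(backsolve(chol(Th), matrix(rnorm(p * n), p, n)))
  list(X = X, theta = Th,
       edges = cbind(1:(p - 1), 2:p))
}

edge_key <- function(e) paste(e[, 1], e[, 2])

test_that("the penalty path is log-spaced with exact endpoints", {
  path <- make_lambda_path(1)
  expect_length(path$values, 40)
  expect_equal(path$values[1], 0.01)
  expect_equal(path$values[40], 1)
  r <- path$values[-1] / path$values[-40]
  expect_equal(r, rep(100^(1 / 39), 39), tolerance = 1e-10)
  expect_equal(make_lambda_path(2)$values[1], 0.02)
  expect_error(make_lambda_path(-1), "positive")
  expect_error(make_lambda_path(1, min_ratio = 2), "min_ratio")
  expect_error(make_lambda_path(1, count = 1), "count")
})

test_that("lambda_max is the largest absolute off-diagonal covariance", {
  expect_equal(compute_lambda_max(diag(3)), 0)
  expect_equal(compute_lambda_max(matrix(c(1, 0.6, 0.6, 1), 2)), 0.6)
  set.seed(5)
  S <- crossprod(matrix(rnorm(40), 8, 5))
  brute <- max(sapply(1:5, function(i) sapply(1:5, function(j)
    if (i == j) 0 else abs(S[i, j]))))
  expect_equal(compute_lambda_max(S), brute)
  expect_error(compute_lambda_max(matrix(1)), "2 x 2")
})

test_that("full shrinkage and independent data give diagonal precision", {
  set.seed(2)
  S <- cov(matrix(rnorm(600), 100, 6))
  f <- fit_prior_glasso(S, NULL, lambda = 10 * compute_lambda_max(S))
  expect_equal(nrow(f$edge_set), 0)
  expect_equal(f$theta, diag(diag(f$theta)), tolerance = 1e-10)
  f2 <- fit_prior_glasso(diag(3), NULL, lambda = 0.1)
  expect_equal(f2$theta, diag(diag(f2$theta)), tolerance = 1e-10)
})

test_that("prior_factor = 1 reduces to the standard graphical lasso (ADMM oracle)", {
  set.seed(42)
  for (p in c(5, 8, 10)) {
    n <- 80
    X <- matrix(rnorm(n * p), n, p) %*% (diag(p) + matrix(rnorm(p * p, sd = 0.25), p, p))
    S <- cov(X)
    lam <- 0.15
    P <- matrix(lam, p, p); diag(P) <- 0
    ref <- admm_glasso(S, P)
    got <- fit_prior_glasso(S, NULL, lam, prior_factor = 1, tol = 1e-9)
    expect_lt(max(abs(got$theta - ref)), 1e-6)
  }
})

test_that("prior weighting relaxes but never removes prior-edge support", {
  set.seed(11)
  p <- 12; n <- 200
  cd <- chain_data(p, n, seed = 11)
  prior <- weighted_graph(sprintf("n%02d", 1:p), {
    A <- matrix(0, p, p); A[cd$edges] <- 1; A + t(A)
  }, sort_nodes = FALSE)
  S <- cov(cd$X)
  lam <- 0.15
  base <- fit_prior_glasso(S, prior, lam, prior_factor = 1)
  relaxed <- fit_prior_glasso(S, prior, lam, prior_factor = 0.05)
  prior_keys <- edge_key(cd$edges)
  kept_base <- intersect(edge_key(base$edge_set), prior_keys)
  expect_true(all(kept_base %in% edge_key(relaxed$edge_set)))
  # every successful fit is positive definite
  expect_silent(chol(base$theta))
  expect_silent(chol(relaxed$theta))
})

test_that("edge support is monotone non-increasing along the penalty path", {
  cd <- chain_data(15, 300, seed = 3)
  S <- cov(cd$X)
  path <- make_lambda_path(compute_lambda_max(S), count = 12)
  sizes <- vapply(path$values, function(l)
    nrow(fit_prior_glasso(S, NULL, l)$edge_set), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("chain-precision support is recovered at small penalties", {
  cd <- chain_data(20, 1000, seed = 7)
  f <- fit_prior_glasso(cov(cd$X), NULL, lambda = 0.08)
  tp <- sum(edge_key(f$edge_set) %in% edge_key(cd$edges))
  prec <- tp / nrow(f$edge_set)
  rec <- tp / nrow(cd$edges)
  f1 <- 2 * prec * rec / (prec + rec)
  expect_gte(f1, 0.8)
})

test_that("the one-SE rule prefers the sparsest model within one SE", {
  lam <- c(0.1, 0.2, 0.4, 0.8)
  # strictly convex, zero SE: degenerates to the minimizer
  expect_equal(spectromics:::one_se_choice(lam, c(5, 2, 3, 6), rep(0, 4)), 0.2)
  # flat curve: the largest penalty wins
  expect_equal(spectromics:::one_se_choice(lam, rep(1, 4), rep(0, 4)), 0.8)
  # one SE of slack admits the sparser neighbour
  expect_equal(spectromics:::one_se_choice(lam, c(5, 2, 2.5, 6), c(1, 1, 1, 1)), 0.4)
  expect_equal(spectromics:::one_se_choice(lam, c(5, 2, 2.5, 6), c(1, 1, 1, 1),
                                           rule = "min"), 0.2)
})

test_that("cross-validated selection lands near the F1-optimal penalty", {
  cd <- chain_data(20, 400, seed = 13)
  S <- cov(cd$X)
  path <- make_lambda_path(compute_lambda_max(S), count = 20)
  sel <- select_lambda(cd$X, NULL, path, seed = 13)
  f1s <- vapply(path$values, function(l) {
    f <- fit_prior_glasso(S, NULL, l)
    if (nrow(f$edge_set) == 0) return(0)
    tp <- sum(edge_key(f$edge_set) %in% edge_key(cd$edges))
    prec <- tp / nrow(f$edge_set); rec <- tp / nrow(cd$edges)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  best <- path$values[which.max(f1s)]
  expect_lte(sel$chosen_lambda / best, 4)
  expect_gte(sel$chosen_lambda / best, 1 / 4)
  # report table covers the whole path
  expect_equal(nrow(sel$table), 20)
  expect_true(all(is.finite(sel$table$mean_bic)))
})

test_that("refine_network returns a graph aligned to the prior's node order", {
  cd <- chain_data(10, 300, seed = 21)
  ids <- sprintf("n%02d", 1:10)
  prior <- weighted_graph(ids, {
    A <- matrix(0, 10, 10); A[cd$edges] <- 1; A + t(A)
  }, sort_nodes = FALSE)
  colnames(cd$X) <- ids
  ref <- refine_network(cd$X, prior, count = 8, seed = 2)
  expect_equal(ref$graph$node_ids, ids)
  expect_s3_class(ref$fit, "precision_estimate")
  expect_true(ref$selection$chosen_lambda %in% ref$path$values)
})
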