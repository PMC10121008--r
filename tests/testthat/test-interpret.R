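test_that("a constant model attributes nothing", {
  bg <- matrix(rnorm(40), 10, 4)
  xs <- matrix(rnorm(8), 2, 4)
  ex <- shap_explain(function(m) rep(0.42, nrow(m)), bg, xs,
                     n_samples = 200, seed = 1)
  expect_equal(ex$base_value, 0.42)
  expect_equal(max(abs(ex$values)), 0, tolerance = 1e-10)
})

test_that("linear models receive their closed-form Shapley attributions", {
  set.seed(3)
  M <- 6
  w <- rnorm(M)
  bg <- matrix(rnorm(50 * M), 50, M)
  f <- function(m) as.numeric(m %*% w) * 0.1 + 0.5
  xs <- matrix(rnorm(2 * M), 2, M)
  ex <- shap_explain(f, bg, xs, n_samples = 200, seed = 2)   # 2^6-2 = 62: exact
  mu <- colMeans(bg)
  for (i in 1:2) {
    want <- 0.1 * w * (xs[i, ] - mu)
    expect_equal(unname(ex$values[i, ]), want, tolerance = 0.05 * max(abs(want)))
  }
  # local accuracy is exact by construction
  expect_equal(ex$base_value + rowSums(ex$values), ex$outputs, tolerance = 1e-10)
})

test_that("irrelevant features receive (near-)zero attribution", {
  set.seed(4)
  bg <- matrix(rnorm(200), 50, 4)
  f <- function(m) 1 / (1 + exp(-m[, 1]))
  xs <- matrix(rnorm(4), 1, 4)
  ex <- shap_explain(f, bg, xs, n_samples = 500, seed = 3)
  expect_lt(max(abs(ex$values[1, 2:4])), 1e-3)
  expect_gt(abs(ex$values[1, 1]), 0.01)
})

test_that("duplicate features are attributed symmetrically", {
  set.seed(5)
  z <- rnorm(60)
  bg <- cbind(z, z, matrix(rnorm(180), 60, 3))
  colnames(bg) <- paste0("f", 1:5)
  f <- function(m) 0.3 * m[, 1] + 0.3 * m[, 2] + 0.2 * m[, 3]
  x <- matrix(c(1.3, 1.3, 0.2, -0.5, 0.9), 1)
  colnames(x) <- colnames(bg)
  ex <- shap_explain(f, bg, x, n_samples = 5000, seed = 4)  # exhaustive at M=5
  expect_equal(unname(ex$values[1, "f1"]), unname(ex$values[1, "f2"]),
               tolerance = 1e-8)
})

test_that("Monte-Carlo sampling still satisfies additivity and finds signal", {
  set.seed(6)
  M <- 40                                    # too wide to enumerate
  bg <- matrix(rnorm(30 * M), 30, M)
  w <- c(2, -1.5, rep(0, M - 2))
  f <- function(m) as.numeric(m %*% w)
  x <- matrix(rnorm(M), 1, M)
  ex <- shap_explain(f, bg, x, n_samples = 800, seed = 5)
  expect_equal(ex$base_value + sum(ex$values[1, ]), ex$outputs[1],
               tolerance = 1e-8)
  rk <- rank_features(ex)
  expect_true(all(rk$feature[1:2] %in% c("f1", "f2")))
})

test_that("global ranking averages absolute attributions with name ties", {
  ex <- structure(list(values = matrix(c(1, -2), 1,
                                       dimnames = list(NULL, c("f1", "f2"))),
                       feature_names = c("f1", "f2"), base_value = 0),
                  class = "shap_explanation")
  rk <- rank_features(ex)
  expect_equal(rk$feature, c("f2", "f1"))
  expect_equal(rk$score, c(2, 1))
  ex$values <- matrix(c(1, -1, 0, 0), 2,
                      dimnames = list(NULL, c("f1", "f2")))
  rk <- rank_features(ex)
  expect_equal(rk$score[rk$feature == "f1"], 1)
  expect_equal(rk$score[rk$feature == "f2"], 0)
  # all-zero attributions: alphabetical order
  ex$values <- matrix(0, 2, 2, dimnames = list(NULL, c("fb", "fa")))
  ex$feature_names <- c("fb", "fa")
  expect_equal(rank_features(ex)$feature, c("fa", "fb"))
  # ranking is invariant to sample order
  set.seed(7)
  v <- matrix(rnorm(20), 4, 5, dimnames = list(NULL, paste0("f", 1:5)))
  exa <- structure(list(values = v, feature_names = paste0("f", 1:5)),
                   class = "shap_explanation")
  exb <- exa; exb$values <- v[4:1, ]
  expect_identical(rank_features(exa), rank_features(exb))
})

test_that("subnetwork extraction drops isolated nodes and finds components", {
  A <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  A["a", "b"] <- A["b", "a"] <- 1
  A["d", "e"] <- A["e", "d"] <- 1
  g <- weighted_graph(letters[1:5], A)
  rk <- structure(data.frame(feature = c("a", "b", "c"), score = c(3, 2, 1)),
                  class = c("importance_ranking", "data.frame"))
  sub <- extract_subnetwork(rk, g, top_k = 3)
  expect_setequal(sub$nodes, c("a", "b"))
  expect_equal(sub$dropped_isolated, "c")
  expect_length(sub$components, 1)
  # fully connected top set: everything retained
  rk2 <- structure(data.frame(feature = c("d", "e"), score = c(2, 1)),
                   class = c("importance_ranking", "data.frame"))
  sub2 <- extract_subnetwork(rk2, g, top_k = 2)
  expect_setequal(sub2$nodes, c("d", "e"))
  # edgeless top set: empty subnetwork
  rk3 <- structure(data.frame(feature = c("a", "d"), score = c(2, 1)),
                   class = c("importance_ranking", "data.frame"))
  expect_length(extract_subnetwork(rk3, g, top_k = 2)$nodes, 0)
  expect_error(extract_subnetwork(rk, g, top_k = 10), "top_k")
})

test_that("channel-level features collapse to nodes by maximum score", {
  A <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  A["a", "b"] <- A["b", "a"] <- 1
  g <- weighted_graph(c("a", "b", "c"), A)
  rk <- structure(data.frame(
    feature = c("a_mrna", "c_protein", "b_mrna", "a_protein", "b_protein", "c_mrna"),
    score = c(5, 4, 3, 2, 1, 0.5)),
    class = c("importance_ranking", "data.frame"))
  sub <- extract_subnetwork(rk, g, top_k = 2)
  # node scores: a = 5, c = 4, b = 3 -> top 2 = {a, c}; edge only a-b -> empty
  expect_equal(sub$selected, c("a", "c"))
  expect_length(sub$nodes, 0)
})

test_that("local reports decompose a prediction exactly", {
  ex <- structure(list(values = matrix(c(0.3, -0.1), 1,
                                       dimnames = list(NULL, c("f1", "f2"))),
                       feature_names = c("f1", "f2"), base_value = 0.5),
                  class = "shap_explanation")
  lr <- local_report(ex, 1, top_m = 2)
  expect_equal(lr$output, 0.7)
  expect_equal(lr$table$feature, c("f1", "f2"))
  expect_equal(lr$table$cumulative, c(0.8, 0.7))
  expect_equal(lr$remainder, 0)
  # top_m larger than the feature count returns everything
  lr2 <- local_report(ex, 1, top_m = 10)
  expect_equal(nrow(lr2$table), 2)
  # truncated report: reported + remainder = output - base, exactly as stored
  ex$values <- matrix(c(0.3, -0.1, 0.05), 1,
                      dimnames = list(NULL, paste0("f", 1:3)))
  ex$feature_names <- paste0("f", 1:3)
  lr3 <- local_report(ex, 1, top_m = 2)
  expect_equal(sum(lr3$table$attribution) + lr3$remainder,
               lr3$output - lr3$base_value)
  expect_error(local_report(ex, 5), "out of range")
})

test_that("large backgrounds are summarized to medoids drawn from the data", {
  set.seed(8)
  bg <- matrix(rnorm(400 * 3), 400, 3)
  red <- spectromics:::background_medoids(bg, 20)
  expect_lte(nrow(red), 20)
  # every medoid is an actual background row
  expect_true(all(apply(red, 1, function(r)
    any(colSums(abs(t(bg) - r)) < 1e-12))))
})
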