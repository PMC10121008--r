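test_that("generated precision matrices are positive definite by construction", {
  for (gm in c("er", "scale_free", "block")) {
    sp <- synth_spec(p = 40, n = 20, graph_model = gm, avg_degree = 4,
                     signal_size = 6, seed = 5)
    gg <- generate_graph(sp)
    expect_silent(chol(gg$precision))
    # support of the precision matches the graph edges
    off <- gg$precision; diag(off) <- 0
    expect_equal(abs(off) > 0, as.matrix(gg$graph$adjacency) > 0,
                 ignore_attr = TRUE)
    # planted subnetwork is connected within the graph
    idx <- match(gg$signal_nodes, gg$graph$node_ids)
    sub <- as.matrix(gg$graph$adjacency)[idx, idx]
    expect_equal(count_components(sub), 1)
  }
})

test_that("generation is deterministic under the seed", {
  sp <- synth_spec(p = 30, n = 50, seed = 77)
  a <- generate_omics(generate_graph(sp), sp)
  b <- generate_omics(generate_graph(sp), sp)
  expect_identical(a$tensor$x, b$tensor$x)
  expect_identical(a$graph$adjacency, b$graph$adjacency)
  expect_identical(a$truth$signal_nodes, b$truth$signal_nodes)
})

test_that("edge density tracks the requested average degree", {
  sp <- synth_spec(p = 200, n = 10, graph_model = "er", avg_degree = 6,
                   seed = 3)
  gg <- generate_graph(sp)
  dens <- graph_density(gg$graph)
  target <- 6 / 199
  expect_lt(abs(dens - target) / target, 0.3)
})

test_that("labels are balanced and both channels carry the class shift", {
  sp <- synth_spec(p = 50, n = 101, avg_degree = 4, signal_size = 8,
                   delta = 1.5, class_balance = 0.5, seed = 21)
  ds <- generate_omics(generate_graph(sp), sp)
  expect_lte(abs(sum(ds$tensor$labels) - 50.5), 0.5)
  sig <- match(ds$truth$signal_nodes, ds$tensor$node_ids)
  for (ch in 1:2) {
    d <- colMeans(ds$tensor$x[ds$tensor$labels == 1, sig, ch]) -
      colMeans(ds$tensor$x[ds$tensor$labels == 0, sig, ch])
    expect_gt(mean(d), 0)
  }
})

test_that("rho controls the cross-channel correlation", {
  sp1 <- synth_spec(p = 30, n = 60, rho = 1, seed = 8, signal_size = 5)
  ds1 <- generate_omics(generate_graph(sp1), sp1)
  expect_equal(ds1$tensor$x[, , 1], ds1$tensor$x[, , 2], tolerance = 1e-12)
  sp2 <- synth_spec(p = 40, n = 500, rho = 0.5, avg_degree = 4,
                    signal_size = 6, seed = 9)
  ds2 <- generate_omics(generate_graph(sp2), sp2)
  null_nodes <- setdiff(seq_len(40), match(ds2$truth$signal_nodes,
                                           ds2$tensor$node_ids))
  cors <- vapply(null_nodes, function(j)
    cor(ds2$tensor$x[, j, 1], ds2$tensor$x[, j, 2]), numeric(1))
  expect_lt(abs(mean(cors) - 0.5), 0.1)
})

test_that("with delta = 0 per-node tests reject at the nominal rate", {
  sp <- synth_spec(p = 150, n = 200, delta = 0, avg_degree = 4,
                   signal_size = 6, seed = 31)
  ds <- generate_omics(generate_graph(sp), sp)
  y <- ds$tensor$labels
  pvals <- apply(ds$tensor$x[, , 1], 2, function(v)
    t.test(v[y == 1], v[y == 0])$p.value)
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.10)
})

test_that("benchmark bundles round-trip losslessly through the readers", {
  sp <- synth_spec(p = 40, n = 30, avg_degree = 4, signal_size = 6, seed = 12)
  dir <- tempfile()
  ds <- make_benchmark(sp, dir = dir)
  g2 <- read_edge_list(ds$paths$graph, score_threshold = 0)
  expect_equal(g2$node_ids, ds$graph$node_ids)
  expect_equal(as.matrix(g2$adjacency), as.matrix(ds$graph$adjacency),
               tolerance = 1e-12)
  m1 <- read_omics_matrix(ds$paths$mrna)
  expect_equal(unname(m1), unname(ds$tensor$x[, , 1]), tolerance = 1e-12)
  expect_equal(colnames(m1), ds$graph$node_ids)
  lab <- read.table(ds$paths$labels, header = TRUE, sep = "\t")
  expect_equal(lab$label, ds$tensor$labels)
  truth <- jsonlite::read_json(ds$paths$truth, simplifyVector = TRUE)
  expect_true(all(truth$signal_nodes %in% ds$graph$node_ids))
  # byte-identical regeneration under the same seed
  dir2 <- tempfile()
  make_benchmark(sp, dir = dir2)
  for (f in c("graph.tsv", "mrna.tsv", "protein.tsv", "labels.tsv", "truth.json"))
    expect_identical(unname(tools::md5sum(file.path(dir, f))),
                     unname(tools::md5sum(file.path(dir2, f))))
})

test_that("network refinement recovers the generating graph from samples", {
  # parameter-recovery loop: one-SE-selected penalty with the true graph as
  # prior should find most true edges with few false ones
  for (seed in c(101, 202, 303)) {
    sp <- synth_spec(p = 50, n = 1000, graph_model = "er", avg_degree = 4,
                     signal_size = 8, seed = seed)
    gg <- generate_graph(sp)
    ds <- generate_omics(gg, sp)
    X <- ds$tensor$x[, , 1]
    S <- cov(X)
    path <- make_lambda_path(compute_lambda_max(S))
    sel <- select_lambda(X, gg$graph, path, seed = seed)
    fit <- fit_prior_glasso(S, gg$graph, sel$chosen_lambda, n_obs = nrow(X))
    truth <- which(gg$precision != 0 & row(gg$precision) < col(gg$precision),
                   arr.ind = TRUE)
    key <- function(e) paste(e[, 1], e[, 2])
    tp <- sum(key(fit$edge_set) %in% key(truth))
    expect_gte(tp / nrow(truth), 0.8)                 # recall
    expect_lte(1 - tp / nrow(fit$edge_set), 0.2)      # false discovery
  }
})

test_that("invalid specifications are rejected", {
  expect_error(synth_spec(p = 2), "p must")
  expect_error(synth_spec(signal_size = 300), "larger")
  expect_error(synth_spec(rho = 1.4), "rho")
  expect_error(synth_spec(class_balance = 0), "class_balance")
  expect_error(synth_spec(avg_degree = 0), "avg_degree")
})
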