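#' Specification of a synthetic multi-omics benchmark
#'
#' Describes the stated world the generator draws from: a sparse PPI-like
#' graph, a Gaussian graphical model consistent with it, and two correlated
#' omics channels (mRNA and protein on the same node set) whose class signal
#' is a mean shift on a planted connected subnetwork. Defaults define the
#' package's standard benchmark: p = 200 nodes, n = 400 samples, a 12-node
#' planted subnetwork with effect size delta = 0.8 (in marginal-SD units),
#' cross-omics correlation rho = 0.5, scale-free topology with average degree
#' 6, balanced classes, seed 7.
#'
#' @param p number of nodes (>= 4).
#' @param n number of samples.
#' @param graph_model `"scale_free"`, `"er"`, or `"block"`.
#' @param avg_degree target average degree.
#' @param signal_size planted subnetwork size.
#' @param delta class mean shift on planted nodes, in units of each node's
#'   marginal SD.
#' @param rho cross-omics correlation in \[0, 1\].
#' @param class_balance fraction of class-1 samples.
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @return a `synth_spec` list.
#' @export
synth_spec <- function(p = 200L, n = 400L,
                       graph_model = c("scale_free", "er", "block"),
                       avg_degree = 6, signal_size = 12L, delta = 0.8,
                       rho = 0.5, class_balance = 0.5, seed = 7L) {
  graph_model <- match.arg(graph_model)
  if (p < 4) stop("p must be >= 4")
  if (signal_size > p) stop("signal subnetwork larger than the graph")
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  if (class_balance <= 0 || class_balance >= 1) stop("class_balance in (0,1)")
  if (avg_degree <= 0 || avg_degree >= p) stop("invalid avg_degree")
  structure(list(p = as.integer(p), n = as.integer(n),
                 graph_model = graph_model, avg_degree = avg_degree,
                 signal_size = as.integer(signal_size), delta = delta,
                 rho = rho, class_balance = class_balance,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Draw a PPI-like graph with a planted connected subnetwork and its GGM
#'
#' The graph is drawn from the requested random-graph model with edge
#' confidences uniform on \[0.4, 1\] (the retained range of a
#' medium-confidence interaction network). A connected `signal_size`-node
#' region is planted by breadth-first growth from a random node; draws whose
#' largest component cannot host it are rejected (up to 20 redraws). The
#' generating precision matrix is diagonally dominant, hence positive
#' definite: Theta = (d_max + 0.5) I + signed edge weights, with d_max the
#' maximum absolute row sum of the signed weights.
#'
#' @param spec a [synth_spec()].
#' @return list: `graph` ([weighted_graph()]), `precision` (dense p x p),
#'   `signal_nodes` (character), `sigma_diag` (marginal variances).
#' @export
generate_graph <- function(spec) {
  p <- spec$p
  ids <- sprintf("g%04d", seq_len(p))
  with_seed(spec$seed, {
    for (try in seq_len(20)) {
      g <- switch(spec$graph_model,
        er = igraph::sample_gnm(p, round(spec$avg_degree * p / 2)),
        scale_free = igraph::sample_pa(p, m = max(1, round(spec$avg_degree / 2)),
                                       directed = FALSE),
        block = {
          b <- 4
          sizes <- rep(p %/% b, b); sizes[1] <- sizes[1] + p %% b
          target <- spec$avg_degree / p
          pm <- matrix(target * 0.4, b, b); diag(pm) <- target * 2.8
          igraph::sample_sbm(p, pref.matrix = pm, block.sizes = sizes)
        })
      comp <- igraph::components(g)
      if (max(comp$csize) >= spec$signal_size) break
      if (try == 20) stop("could not draw a graph hosting the planted subnetwork")
    }
    el <- igraph::as_edgelist(g, names = FALSE)
    w <- stats::runif(nrow(el), 0.4, 1)
    adj <- Matrix::sparseMatrix(i = c(el[, 1], el[, 2]),
                                j = c(el[, 2], el[, 1]),
                                x = c(w, w), dims = c(p, p))
    graph <- weighted_graph(ids, adj, sort_nodes = FALSE)
    # plant the signal on a BFS ball inside a big-enough component
    big <- which(comp$membership %in% which(comp$csize >= spec$signal_size))
    root <- sample(big, 1)
    ord <- igraph::bfs(g, root = root, order = TRUE)$order
    signal_idx <- as.integer(ord[seq_len(spec$signal_size)])
    # signed, diagonally dominant precision on the edge pattern
    sgn <- sample(c(-1, 1), nrow(el), replace = TRUE)
    theta <- matrix(0, p, p)
    theta[el] <- sgn * w
    theta <- theta + t(theta)
    d_max <- max(rowSums(abs(theta)))
    diag(theta) <- d_max + 0.5
  })
  R <- chol(theta)
  sigma_diag <- diag(chol2inv(R))
  list(graph = graph, precision = theta, signal_nodes = ids[signal_idx],
       sigma_diag = sigma_diag)
}

#' Simulate two correlated omics channels with a planted class signal
#'
#' Labels are balanced Bernoulli (deterministic counts within one sample of
#' the requested balance, order shuffled). The mRNA channel is multivariate
#' normal with covariance `solve(precision)`; class-1 samples get a mean
#' shift of `delta` marginal SDs on the planted nodes. The protein channel is
#' `rho * mRNA + sqrt(1 - rho^2) * independent-draw`, the independent draw
#' carrying the same class shift, so both channels are informative and their
#' cross-channel correlation at null nodes is `rho`. No standardization is
#' applied here — that belongs to the modelling stage.
#'
#' @param gg a [generate_graph()] result.
#' @param spec the same [synth_spec()].
#' @return object of class `synth_dataset`: `graph`, `tensor`
#'   ([omics_tensor()], channels `mrna`, `protein`), `truth` (signal nodes
#'   and precision), `spec`.
#' @export
generate_omics <- function(gg, spec) {
  p <- spec$p; n <- spec$n
  R <- chol(gg$precision)
  sig_idx <- match(gg$signal_nodes, gg$graph$node_ids)
  shift <- rep(0, p)
  shift[sig_idx] <- spec$delta * sqrt(gg$sigma_diag[sig_idx])
  with_seed(spec$seed + 1L, {
    n1 <- round(n * spec$class_balance)
    labels <- sample(rep(c(1L, 0L), c(n1, n - n1)))
    mu <- outer(labels, shift)             # n x p class-dependent mean
    draw <- function() t(backsolve(R, matrix(stats::rnorm(p * n), p, n)))
    x1 <- mu + draw()
    x2 <- spec$rho * x1 + sqrt(1 - spec$rho^2) * (mu + draw())
  })
  colnames(x1) <- colnames(x2) <- gg$graph$node_ids
  tensor <- omics_tensor(list(mrna = x1, protein = x2), labels,
                         node_ids = gg$graph$node_ids)
  structure(list(graph = gg$graph, tensor = tensor,
                 truth = list(signal_nodes = gg$signal_nodes,
                              precision = gg$precision),
                 spec = spec),
            class = "synth_dataset")
}

#' Generate and (optionally) write the standard benchmark bundle
#'
#' Draws the graph and omics under the spec and, when `dir` is given, writes
#' the file bundle consumed by the pipeline readers: `graph.tsv` (edge list),
#' `mrna.tsv` and `protein.tsv` (samples x nodes, header = node ids),
#' `labels.tsv` (sample, label), and `truth.json` (signal nodes, spec).
#'
#' @param spec a [synth_spec()]; the default is the repository's standard
#'   fixture.
#' @param dir optional output directory.
#' @return the `synth_dataset`, with `$paths` when files were written.
#' @export
make_benchmark <- function(spec = synth_spec(), dir = NULL) {
  gg <- generate_graph(spec)
  ds <- generate_omics(gg, spec)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(graph = file.path(dir, "graph.tsv"),
                  mrna = file.path(dir, "mrna.tsv"),
                  protein = file.path(dir, "protein.tsv"),
                  labels = file.path(dir, "labels.tsv"),
                  truth = file.path(dir, "truth.json"))
    write_edge_list(ds$graph, paths$graph)
    write_omics_matrix(ds$tensor$x[, , 1], ds$graph$node_ids, paths$mrna)
    write_omics_matrix(ds$tensor$x[, , 2], ds$graph$node_ids, paths$protein)
    utils::write.table(data.frame(sample = sprintf("s%04d", seq_len(spec$n)),
                                  label = ds$tensor$labels),
                       paths$labels, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(signal_nodes = ds$truth$signal_nodes,
                              spec = unclass(spec)),
                         paths$truth, auto_unbox = TRUE, digits = NA)
    ds$paths <- paths
  }
  ds
}

write_omics_matrix <- function(x, node_ids, path) {
  colnames(x) <- node_ids
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a samples x nodes omics matrix (header = node ids)
#' @param path delimited text file written by [write_omics_matrix()] or
#'   compatible (tab-separated, header row of node identifiers).
#' @return numeric matrix with column names.
#' @export
read_omics_matrix <- function(path) {
  as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                              check.names = FALSE))
}
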