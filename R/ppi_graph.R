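#' Construct a weighted undirected graph on a fixed node order
#'
#' `weighted_graph()` is the basic container used throughout the package: an
#' ordered node set plus a sparse symmetric nonnegative adjacency matrix with a
#' zero diagonal. All downstream arrays (omics tensors, Laplacians, coarsening
#' hierarchies) inherit this node order, which is fixed once at construction.
#'
#' @param node_ids character vector of unique node identifiers.
#' @param adjacency symmetric nonnegative p x p matrix (dense or
#'   `Matrix` sparse) with zero diagonal; rows/columns follow `node_ids`.
#' @param weighted logical; `FALSE` marks a binary (presence/absence) graph.
#' @param sort_nodes if `TRUE` (default) nodes are reordered lexicographically
#'   so the node order is reproducible regardless of input order.
#' @return An object of class `weighted_graph` with elements `node_ids`,
#'   `adjacency` (a `dgCMatrix`), and `weighted`.
#' @export
weighted_graph <- function(node_ids, adjacency, weighted = TRUE,
                           sort_nodes = TRUE) {
  node_ids <- as.character(node_ids)
  p <- length(node_ids)
  if (anyDuplicated(node_ids)) stop("node_ids must be unique")
  adjacency <- methods::as(methods::as(Matrix::Matrix(adjacency, sparse = TRUE),
                                       "generalMatrix"), "CsparseMatrix")
  if (nrow(adjacency) != p || ncol(adjacency) != p)
    stop("adjacency dimensions do not match node_ids")
  if (p > 0 && max(abs(adjacency - Matrix::t(adjacency))) > 1e-12)
    stop("adjacency must be symmetric (within 1e-12)")
  if (any(Matrix::diag(adjacency) != 0)) stop("adjacency must have zero diagonal")
  if (p > 0 && length(adjacency@x) && min(adjacency@x) < 0)
    stop("edge weights must be nonnegative")
  if (sort_nodes && p > 1) {
    o <- order(node_ids)
    node_ids <- node_ids[o]
    adjacency <- adjacency[o, o, drop = FALSE]
  }
  dimnames(adjacency) <- list(node_ids, node_ids)
  structure(list(node_ids = node_ids, adjacency = Matrix::drop0(adjacency),
                 weighted = weighted),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  p <- length(x$node_ids)
  ne <- graph_edge_count(x)
  cat(sprintf("weighted_graph: %d nodes, %d edges (%s)\n", p, ne,
              if (x$weighted) "weighted" else "binary"))
  invisible(x)
}

graph_edge_count <- function(graph) {
  length(graph$adjacency@x[graph$adjacency@x != 0]) / 2L
}

#' Read a STRING-style edge list into a weighted graph
#'
#' Parses a whitespace/tab-delimited text file with three columns per line
#' (`node_a node_b score`), ignoring blank lines and lines starting with `#`.
#' Two score dialects are auto-detected: probabilities already in \[0, 1\],
#' or STRING-style integer scores in 0--1000, which are divided by 1000 when
#' any score exceeds 1. Edges below `score_threshold` (after normalization)
#' are discarded; 0.4 is STRING's "medium confidence" default. Duplicate and
#' reciprocal edge lines are collapsed keeping the maximum score, and
#' self-loops are dropped.
#'
#' @param path path to the edge-list file.
#' @param score_threshold minimum retained edge score, default 0.4.
#' @param binarize if `TRUE`, retained edges get weight 1 (score used for
#'   thresholding only).
#' @return a [weighted_graph].
#' @export
read_edge_list <- function(path, score_threshold = 0.4, binarize = FALSE) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) {
    return(weighted_graph(character(0),
                          Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                               x = numeric(0), dims = c(0, 0)),
                          weighted = !binarize))
  }
  parts <- strsplit(trimws(lines[idx]), "[\t ,]+")
  nf <- lengths(parts)
  if (any(nf != 3L))
    stop(sprintf("malformed edge line %d: expected 'node_a node_b score', got %s",
                 idx[which(nf != 3L)[1L]], shQuote(lines[idx[which(nf != 3L)[1L]]])))
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  score <- suppressWarnings(as.numeric(m[, 3L]))
  if (anyNA(score))
    stop(sprintf("malformed edge line %d: non-numeric score", idx[which(is.na(score))[1L]]))
  if (any(score < 0))
    stop(sprintf("negative score on line %d", idx[which(score < 0)[1L]]))
  if (any(score > 1)) score <- score / 1000   # STRING integer dialect
  a <- m[, 1L]; b <- m[, 2L]
  ok <- score >= score_threshold & a != b
  a <- a[ok]; b <- b[ok]; score <- score[ok]
  ids <- sort(unique(c(a, b)))
  p <- length(ids)
  i <- match(a, ids); j <- match(b, ids)
  lo <- pmin(i, j); hi <- pmax(i, j)
  # collapse duplicates / reciprocals, keeping max score
  key <- (lo - 1) * p + hi
  if (anyDuplicated(key)) {
    mx <- tapply(score, key, max)
    key <- as.numeric(names(mx))
    score <- as.numeric(mx)
    lo <- (key - 1) %/% p + 1
    hi <- (key - 1) %% p + 1
  }
  w <- if (binarize) rep(1, length(score)) else score
  adj <- Matrix::sparseMatrix(i = c(lo, hi), j = c(hi, lo), x = c(w, w),
                              dims = c(p, p))
  weighted_graph(ids, adj, weighted = !binarize, sort_nodes = TRUE)
}

#' Write a graph back out as an edge-list TSV
#'
#' Inverse of [read_edge_list()] for retained edges; each undirected edge is
#' written once (`node_a < node_b` lexicographically).
#' @param graph a [weighted_graph].
#' @param path output file.
#' @export
write_edge_list <- function(graph, path) {
  a <- graph$adjacency
  tri <- Matrix::which(a != 0, arr.ind = TRUE)
  tri <- tri[tri[, 1] < tri[, 2], , drop = FALSE]
  df <- data.frame(node_a = graph$node_ids[tri[, 1]],
                   node_b = graph$node_ids[tri[, 2]],
                   score = a[tri])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Map omics feature identifiers onto graph nodes, one-to-one
#'
#' Features whose target identifier cannot be matched uniquely and
#' bidirectionally to a graph node are dropped, mirroring the rule used for
#' aptamer-to-gene-symbol mapping: if two features map to the same node, both
#' are removed; features mapping to no node are removed. Drops are logged, not
#' fatal.
#'
#' @param feature_ids character vector of target node identifiers, one per
#'   feature. Names, if present, are the feature names (defaulting to the
#'   targets themselves).
#' @param graph a [weighted_graph].
#' @return a `node_map`: list with `feature_id` -> `node_index` data frame
#'   (`mapping`) and a `dropped` data frame (`feature`, `reason` in
#'   `duplicate-feature`, `duplicate-target`, `no-node`).
#' @export
map_features_to_nodes <- function(feature_ids, graph) {
  targets <- as.character(feature_ids)
  feats <- names(feature_ids)
  if (is.null(feats)) feats <- targets
  drop <- data.frame(feature = character(0), reason = character(0),
                     stringsAsFactors = FALSE)
  dup_f <- feats %in% feats[duplicated(feats)]
  if (any(dup_f))
    drop <- rbind(drop, data.frame(feature = feats[dup_f], reason = "duplicate-feature"))
  keep <- !dup_f
  miss <- keep & !(targets %in% graph$node_ids)
  if (any(miss))
    drop <- rbind(drop, data.frame(feature = feats[miss], reason = "no-node"))
  keep <- keep & !miss
  # two (remaining) features pointing at the same node: all of them go
  tt <- targets[keep]
  dup_t <- targets %in% tt[duplicated(tt)] & keep
  if (any(dup_t))
    drop <- rbind(drop, data.frame(feature = feats[dup_t], reason = "duplicate-target"))
  keep <- keep & !dup_t
  mapping <- data.frame(feature = feats[keep],
                        node_index = match(targets[keep], graph$node_ids),
                        stringsAsFactors = FALSE)
  structure(list(mapping = mapping, dropped = drop), class = "node_map")
}

#' Write a node-map drop log as TSV
#' @param node_map result of [map_features_to_nodes()].
#' @param path output file.
#' @export
write_drop_log <- function(node_map, path) {
  utils::write.table(node_map$dropped, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Graph Laplacian with largest-eigenvalue estimate
#'
#' The combinatorial Laplacian is L = D - A with D the diagonal weighted-degree
#' matrix; the symmetric-normalized variant is I - D^{-1/2} A D^{-1/2}, with
#' zero-degree rows left as identity rows. `lambda_max` is computed by a dense
#' symmetric eigensolver for p <= 2000 and by power iteration (tolerance 1e-6,
#' at most 500 iterations) beyond that.
#'
#' @param graph a [weighted_graph].
#' @param kind `"combinatorial"` (default, L = D - A) or `"normalized"`.
#' @return list of class `laplacian_matrix`: `matrix` (sparse symmetric),
#'   `kind`, `lambda_max`.
#' @export
build_laplacian <- function(graph, kind = c("combinatorial", "normalized")) {
  kind <- match.arg(kind)
  a <- graph$adjacency
  if (max(abs(a - Matrix::t(a))) > 1e-12) stop("adjacency must be symmetric")
  p <- nrow(a)
  d <- Matrix::rowSums(a)
  if (kind == "combinatorial") {
    L <- Matrix::Diagonal(p, d) - a
  } else {
    dz <- ifelse(d > 0, 1 / sqrt(d), 0)
    L <- Matrix::Diagonal(p, 1) - Matrix::Diagonal(p, dz) %*% a %*% Matrix::Diagonal(p, dz)
  }
  L <- methods::as(methods::as(L, "generalMatrix"), "CsparseMatrix")
  lmax <- estimate_lambda_max(L)
  structure(list(matrix = L, kind = kind, lambda_max = lmax),
            class = "laplacian_matrix")
}

estimate_lambda_max <- function(L, tol = 1e-6, max_iter = 500L) {
  p <- nrow(L)
  if (p == 0) return(0)
  if (p <= 2000) {
    ev <- eigen(as.matrix(L), symmetric = TRUE, only.values = TRUE)$values
    return(max(ev))
  }
  set.seed(0L)  # internal; lambda_max must not depend on caller RNG state
  v <- rnorm(p); v <- v / sqrt(sum(v^2))
  lam <- 0
  for (it in seq_len(max_iter)) {
    w <- as.numeric(L %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v_new <- w / nw
    lam_new <- as.numeric(crossprod(v_new, L %*% v_new))
    if (abs(lam_new - lam) < tol) return(lam_new)
    lam <- lam_new; v <- v_new
  }
  lam
}

#' Edge density of a graph
#'
#' Fraction of realized node pairs: 2|E| / (p (p - 1)), counting nonzero
#' off-diagonal pairs once.
#' @param graph a [weighted_graph] with at least 2 nodes.
#' @return a scalar in \[0, 1\].
#' @export
graph_density <- function(graph) {
  p <- length(graph$node_ids)
  if (p < 2) stop("density undefined for graphs with fewer than 2 nodes")
  2 * graph_edge_count(graph) / (p * (p - 1))
}
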