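#' Sampling-based Shapley-value explanation of a black-box classifier
#'
#' Kernel-style Shapley estimation: for each explained sample, feature
#' coalitions are drawn (all of them when exhaustively enumerable within the
#' budget, otherwise `n_samples` Monte-Carlo draws with coalition sizes
#' sampled from the Shapley kernel), absent features are imputed from the
#' background rows, and a weighted linear surrogate is fitted to the model's
#' mean outputs under the additivity constraint — so the base value plus the
#' attributions reproduce the model output exactly.
#'
#' The background is summarized to at most `max_background` medoids (seeded
#' k-means, nearest real row per center) for tractability; pass the full
#' training matrix and raise `max_background` to disable the reduction.
#'
#' @param model_fn function mapping an n x M feature matrix to class-1
#'   probabilities (see [predict_proba()] for package models).
#' @param background reference feature matrix (training set), rows = samples.
#' @param samples matrix of rows to explain (same columns as background).
#' @param n_samples coalition draws per explained sample, default 1200.
#' @param seed RNG seed.
#' @param max_background medoid cap on the background, default 100.
#' @param chunk model-call batch size.
#' @return object of class `shap_explanation`: `base_value`, `values`
#'   (n_explained x M), `feature_names`, `n_samples`, `outputs` (model
#'   outputs of the explained rows).
#' @export
shap_explain <- function(model_fn, background, samples, n_samples = 1200L,
                         seed = 1L, max_background = 100L, chunk = 8192L) {
  background <- as.matrix(background)
  samples <- as.matrix(samples)
  if (ncol(background) != ncol(samples))
    stop("background and samples must share columns")
  if (nrow(background) < 1) stop("background must be nonempty")
  M <- ncol(samples)
  feature_names <- colnames(samples) %||% sprintf("f%d", seq_len(M))
  with_seed(seed, {
    if (nrow(background) > max_background)
      background <- background_medoids(background, max_background)
    nb <- nrow(background)
    base_value <- mean(model_fn(background))
    fx <- as.numeric(model_fn(samples))
    values <- matrix(0, nrow(samples), M,
                     dimnames = list(NULL, feature_names))
    exact <- M <= 30 && (2^M - 2) <= n_samples
    for (i in seq_len(nrow(samples))) {
      x <- samples[i, ]
      if (exact) {
        Z <- all_coalitions(M)
        s <- rowSums(Z)
        w <- (M - 1) / (choose(M, s) * s * (M - s))
      } else {
        Z <- sample_coalitions(M, n_samples)
        w <- rep(1, nrow(Z))
      }
      y <- coalition_outputs(model_fn, Z, x, background, chunk)
      values[i, ] <- solve_shap_wls(Z, w, y, base_value, fx[i])
    }
  })
  structure(list(base_value = base_value, values = values,
                 feature_names = feature_names,
                 n_samples = as.integer(n_samples), outputs = fx,
                 background_size = nrow(background)),
            class = "shap_explanation")
}

# all 2^M - 2 non-trivial coalition indicator rows
all_coalitions <- function(M) {
  Z <- as.matrix(expand.grid(rep(list(c(0, 1)), M)))
  dimnames(Z) <- NULL
  s <- rowSums(Z)
  Z[s > 0 & s < M, , drop = FALSE]
}

# coalition sizes follow the Shapley kernel marginal, members uniform
sample_coalitions <- function(M, n) {
  sizes <- seq_len(M - 1)
  pr <- (M - 1) / (sizes * (M - sizes))
  pr <- pr / sum(pr)
  s <- sample(sizes, n, replace = TRUE, prob = pr)
  Z <- matrix(0, n, M)
  for (r in seq_len(n)) Z[r, sample.int(M, s[r])] <- 1
  Z
}

# mean model output per coalition, imputing absent features from background
coalition_outputs <- function(model_fn, Z, x, background, chunk) {
  nb <- nrow(background)
  nz <- nrow(Z)
  out <- numeric(nz)
  per <- max(1L, floor(chunk / nb))
  for (s in seq(1, nz, by = per)) {
    e <- min(s + per - 1, nz)
    idx <- s:e
    # rows: coalition-major blocks of the background
    Xs <- background[rep(seq_len(nb), times = length(idx)), , drop = FALSE]
    zrep <- Z[rep(idx, each = nb), , drop = FALSE]
    xrep <- matrix(x, nrow(Xs), length(x), byrow = TRUE)
    Xs <- zrep * xrep + (1 - zrep) * Xs
    f <- model_fn(Xs)
    out[idx] <- colMeans(matrix(f, nb, length(idx)))
  }
  out
}

# constrained weighted least squares: phi_0 = base, sum(phi) = fx - base
solve_shap_wls <- function(Z, w, y, base_value, fx) {
  M <- ncol(Z)
  e <- fx - base_value
  ytil <- y - base_value - Z[, M] * e
  Xtil <- Z[, -M, drop = FALSE] - Z[, M]
  A <- crossprod(Xtil * w, Xtil)
  diag(A) <- diag(A) + 1e-10 * sum(w)
  phi <- solve(A, crossprod(Xtil * w, ytil))
  c(phi, e - sum(phi))
}

background_medoids <- function(background, k) {
  km <- stats::kmeans(background, centers = k, nstart = 1, iter.max = 50)
  idx <- vapply(seq_len(k), function(j) {
    rows <- which(km$cluster == j)
    d <- rowSums(sweep(background[rows, , drop = FALSE], 2,
                       km$centers[j, ])^2)
    rows[which.min(d)]
  }, integer(1))
  background[sort(unique(idx)), , drop = FALSE]
}

#' Global feature ranking by mean absolute attribution
#'
#' @param explanation a [shap_explain()] result.
#' @return object of class `importance_ranking`: data frame (`feature`,
#'   `score`) in descending score order, ties broken by feature name.
#' @export
rank_features <- function(explanation) {
  if (nrow(explanation$values) < 1) stop("no explained samples")
  score <- colMeans(abs(explanation$values))
  df <- data.frame(feature = explanation$feature_names, score = score,
                   stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$feature), ]
  rownames(df) <- NULL
  structure(df, class = c("importance_ranking", "data.frame"))
}

#' Induced subnetwork of the top-ranked nodes
#'
#' Collapses channel-level features to nodes (maximum score across channels),
#' takes the `top_k` nodes, extracts the induced sub-adjacency from the
#' graph, removes nodes left without any connection, and enumerates connected
#' components.
#'
#' @param ranking an [rank_features()] result (features either node ids or
#'   `<node>_<channel>` names).
#' @param graph the [weighted_graph()] the model was trained on.
#' @param top_k number of top nodes to extract, default 30.
#' @return object of class `subnetwork`: `nodes` (retained, connected),
#'   `selected` (the top_k before isolation removal), `adjacency`,
#'   `components` (membership list), `dropped_isolated`.
#' @export
extract_subnetwork <- function(ranking, graph, top_k = 30L) {
  feats <- ranking$feature
  node <- ifelse(feats %in% graph$node_ids, feats,
                 sub("_[^_]*$", "", feats))
  keep <- node %in% graph$node_ids
  df <- data.frame(node = node[keep], score = ranking$score[keep])
  agg <- stats::aggregate(score ~ node, df, max)
  agg <- agg[order(-agg$score, agg$node), ]
  if (top_k > length(graph$node_ids)) stop("top_k exceeds the node count")
  sel <- utils::head(agg$node, top_k)
  idx <- match(sel, graph$node_ids)
  sub <- graph$adjacency[idx, idx, drop = FALSE]
  deg <- Matrix::rowSums(sub != 0)
  retained <- which(deg > 0)
  sub2 <- sub[retained, retained, drop = FALSE]
  nodes <- sel[retained]
  comps <- if (length(nodes)) {
    g <- igraph::graph_from_adjacency_matrix(sub2 != 0, mode = "undirected")
    mem <- igraph::components(g)$membership
    split(nodes, mem)
  } else list()
  structure(list(nodes = nodes, selected = sel,
                 adjacency = sub2, components = comps,
                 dropped_isolated = sel[deg == 0]),
            class = "subnetwork")
}

#' Ordered local attribution report for one explained sample
#'
#' Lists the `top_m` features by absolute attribution with their signs and
#' the running (cumulative) prediction from the base value; the remainder
#' term makes the decomposition exact.
#'
#' @param explanation a [shap_explain()] result.
#' @param sample_index row of `explanation$values` to report.
#' @param top_m features to list, default 10 (capped at M).
#' @return list with `table` (feature, attribution, cumulative), `base_value`,
#'   `output`, `remainder`.
#' @export
local_report <- function(explanation, sample_index, top_m = 10L) {
  v <- explanation$values
  if (sample_index < 1 || sample_index > nrow(v))
    stop("sample_index out of range")
  phi <- v[sample_index, ]
  o <- order(-abs(phi))
  top_m <- min(top_m, length(phi))
  sel <- o[seq_len(top_m)]
  cum <- explanation$base_value + cumsum(phi[sel])
  tab <- data.frame(feature = explanation$feature_names[sel],
                    attribution = unname(phi[sel]),
                    cumulative = unname(cum), stringsAsFactors = FALSE)
  remainder <- sum(phi[-sel])
  if (top_m == length(phi)) remainder <- 0
  list(table = tab, base_value = explanation$base_value,
       output = explanation$base_value + sum(phi), remainder = remainder)
}

#' Write attribution outputs as TSV files
#'
#' @param explanation a [shap_explain()] result.
#' @param ranking optional [rank_features()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_shap_outputs <- function(explanation, ranking = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vals <- as.data.frame(explanation$values)
  p1 <- file.path(dir, "shap_values.tsv")
  utils::write.table(vals, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- p1
  if (!is.null(ranking)) {
    p2 <- file.path(dir, "shap_ranking.tsv")
    utils::write.table(ranking, p2, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p2)
  }
  invisible(paths)
}
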