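# Run code with a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Multilevel Graclus-style graph coarsening with pseudo-node padding
#'
#' Repeatedly merges node pairs by greedy matching: nodes are visited in
#' ascending weighted-degree order (ties broken by a seeded shuffle), and each
#' unmatched node is merged with the unmatched neighbour maximizing the
#' normalized cut score `w_ij (1/d_i + 1/d_j)`; nodes with no unmatched
#' neighbour stay singletons. After `levels` rounds a balanced tree is built:
#' every coarse node gets exactly `pool_size` children, with zero-signal,
#' zero-edge fake (pseudo) nodes padding short lineages, so stride pooling on
#' contiguous blocks is exact. The number of fake nodes is emergent from the
#' matching, not a constant.
#'
#' @param graph a [weighted_graph()].
#' @param levels number of coarsening rounds (>= 1); a model with `levels`
#'   pooling layers needs a hierarchy at least that deep.
#' @param seed integer seed controlling the visit-order shuffle.
#' @param pool_size children per coarse node (default 2).
#' @return object of class `coarsening_hierarchy`: `graphs` (padded,
#'   position-ordered sparse adjacency per level 0..levels), `parent` (per
#'   round, fine real index -> coarse real index), `perm` (level-0 positions ->
#'   original node index, NA for fakes), `fake` (per level, logical by
#'   position), `sizes` (padded size per level), plus `pool_size`, `node_ids`.
#' @export
graclus_coarsen <- function(graph, levels, seed = 1L, pool_size = 2L) {
  p0 <- length(graph$node_ids)
  if (p0 < 1) stop("cannot coarsen an empty graph")
  if (levels < 1) stop("levels must be >= 1")
  adj <- list(graph$adjacency)
  parent <- vector("list", levels)
  with_seed(seed, {
    for (t in seq_len(levels)) {
      A <- adj[[t]]
      p <- nrow(A)
      d <- Matrix::rowSums(A)
      shuf <- sample.int(p)
      visit <- shuf[order(d[shuf])]          # ascending degree, seeded ties
      cluster <- integer(p)
      nc <- 0L
      for (i in visit) {
        if (cluster[i] > 0L) next
        nc <- nc + 1L
        cluster[i] <- nc
        nb <- which(A[i, ] != 0)
        nb <- nb[cluster[nb] == 0L]
        if (length(nb)) {
          sc <- as.numeric(A[i, nb]) * (1 / d[i] + 1 / d[nb])
          j <- nb[which.max(sc)]
          cluster[j] <- nc
        }
      }
      parent[[t]] <- cluster
      P <- Matrix::sparseMatrix(i = seq_len(p), j = cluster, x = 1,
                                dims = c(p, nc))
      Ac <- Matrix::t(P) %*% A %*% P
      Matrix::diag(Ac) <- 0
      adj[[t + 1]] <- Matrix::drop0(methods::as(methods::as(
        Ac, "generalMatrix"), "CsparseMatrix"))
    }
  })
  # balanced-tree positions: real index, or NA for a fake node
  pos <- vector("list", levels + 1)
  pos[[levels + 1]] <- seq_len(nrow(adj[[levels + 1]]))
  for (l in seq(levels, 1)) {
    par <- parent[[l]]
    out <- integer(0)
    for (c in pos[[l + 1]]) {
      ch <- if (is.na(c)) integer(0) else sort(which(par == c))
      if (length(ch) > pool_size)
        stop("matching produced more children than pool_size")
      length(ch) <- pool_size            # pads with NA
      out <- c(out, ch)
    }
    pos[[l]] <- out
  }
  graphs <- vector("list", levels + 1)
  for (l in seq_along(pos)) {
    m <- length(pos[[l]])
    rp <- which(!is.na(pos[[l]]))
    A <- adj[[l]]
    Ap <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(m, m))
    if (length(rp)) {
      sub <- A[pos[[l]][rp], pos[[l]][rp], drop = FALSE]
      nz <- Matrix::which(sub != 0, arr.ind = TRUE)
      if (nrow(nz)) {
        Ap <- Matrix::sparseMatrix(i = rp[nz[, 1]], j = rp[nz[, 2]],
                                   x = sub[nz], dims = c(m, m))
      }
    }
    graphs[[l]] <- methods::as(methods::as(Ap, "generalMatrix"), "CsparseMatrix")
  }
  structure(list(graphs = graphs,
                 parent = parent,
                 perm = pos[[1]],
                 positions = pos,
                 fake = lapply(pos, is.na),
                 sizes = vapply(pos, length, integer(1)),
                 pool_size = as.integer(pool_size),
                 levels = as.integer(levels),
                 node_ids = graph$node_ids),
            class = "coarsening_hierarchy")
}

#' @export
print.coarsening_hierarchy <- function(x, ...) {
  cat(sprintf("coarsening_hierarchy: %d levels, pool %d, sizes %s, %d fakes at level 0\n",
              x$levels, x$pool_size, paste(x$sizes, collapse = " -> "),
              sum(x$fake[[1]])))
  invisible(x)
}

#' Permute and zero-pad node signals to the hierarchy's level-0 layout
#'
#' Applies the balanced-tree permutation and inserts zeros at fake-node
#' positions, so contiguous blocks of `pool_size` positions are siblings.
#'
#' @param X n x p matrix (or length-p vector, or n x p x C array) aligned to
#'   the original node order of the coarsened graph.
#' @param hierarchy a [graclus_coarsen()] result.
#' @return the padded signal, with p replaced by the padded level-0 size.
#' @export
pad_signal <- function(X, hierarchy) {
  vec <- is.null(dim(X))
  if (vec) X <- matrix(X, 1)
  if (length(dim(X)) == 3) {
    out <- vapply(seq_len(dim(X)[3]),
                  function(c) pad_signal(X[, , c], hierarchy),
                  matrix(0, dim(X)[1], hierarchy$sizes[1]))
    return(array(out, c(dim(X)[1], hierarchy$sizes[1], dim(X)[3])))
  }
  p <- sum(!is.na(hierarchy$perm))
  if (ncol(X) != p)
    stop(sprintf("signal has %d nodes, hierarchy expects %d", ncol(X), p))
  m <- hierarchy$sizes[1]
  out <- matrix(0, nrow(X), m)
  real <- which(!is.na(hierarchy$perm))
  out[, real] <- X[, hierarchy$perm[real]]
  if (vec) out <- drop(out)
  out
}

#' Stride-pooling plan over a coarsening hierarchy
#'
#' Precomputes sparse pooling operators per level. Default `"average"` mode
#' divides every block by `pool_size`, counting fake nodes as zeros (the
#' padding's neutral value); `"real_average"` divides by the number of real
#' leaves in the block (minimum 1) instead; `"max"` takes the block maximum.
#'
#' @param hierarchy a [graclus_coarsen()] result.
#' @param kind `"average"`, `"real_average"`, or `"max"`.
#' @return object of class `pool_plan`.
#' @export
pool_plan <- function(hierarchy, kind = c("average", "real_average", "max")) {
  kind <- match.arg(kind)
  ps <- hierarchy$pool_size
  ops <- vector("list", hierarchy$levels)
  counts <- vector("list", hierarchy$levels)
  for (l in seq_len(hierarchy$levels)) {
    m <- hierarchy$sizes[l]
    mc <- hierarchy$sizes[l + 1]
    blk <- rep(seq_len(mc), each = ps)
    real_cnt <- tapply(!hierarchy$fake[[l]], blk, sum)
    counts[[l]] <- as.integer(real_cnt)
    w <- if (kind == "real_average") rep(1 / pmax(real_cnt, 1), each = ps)
         else rep(1 / ps, m)
    ops[[l]] <- Matrix::sparseMatrix(i = seq_len(m), j = blk, x = w,
                                     dims = c(m, mc))
  }
  structure(list(kind = kind, ops = ops, pool_size = ps,
                 real_leaf_counts = counts, sizes = hierarchy$sizes),
            class = "pool_plan")
}

#' Pool a padded node signal one level up the hierarchy
#'
#' @param signal n x m matrix (or length-m vector) in the padded,
#'   position-ordered layout of `level`.
#' @param plan a [pool_plan()].
#' @param level level being pooled from (1 = finest), default 1.
#' @return pooled signal of padded size at `level + 1`.
#' @export
pool <- function(signal, plan, level = 1L) {
  vec <- is.null(dim(signal))
  if (vec) signal <- matrix(signal, 1)
  if (ncol(signal) == 0) stop("cannot pool a zero-length signal")
  if (ncol(signal) != plan$sizes[level])
    stop(sprintf("signal length %d does not match level size %d",
                 ncol(signal), plan$sizes[level]))
  out <- if (plan$kind == "max") {
    ps <- plan$pool_size
    mc <- plan$sizes[level + 1]
    res <- matrix(-Inf, nrow(signal), mc)
    for (k in seq_len(ps))
      res <- pmax(res, signal[, seq(k, by = ps, length.out = mc), drop = FALSE])
    res
  } else {
    as.matrix(signal %*% plan$ops[[level]])
  }
  if (vec) out <- drop(out)
  out
}
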