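#' Annotation term sets restricted to a declared background
#'
#' Gene/protein sets (e.g. GO terms) are intersected with the background
#' universe — the features the model was actually trained on — and terms with
#' no background member are dropped. All enrichment counts downstream are
#' computed against this background only.
#'
#' @param sets named list: term id -> character vector of member gene ids.
#' @param background character vector, the feature universe.
#' @param term_names optional named character vector of display names.
#' @return object of class `annotation_map`.
#' @export
annotation_map <- function(sets, background, term_names = NULL) {
  background <- unique(as.character(background))
  sets <- lapply(sets, function(g) intersect(unique(as.character(g)), background))
  keep <- lengths(sets) > 0
  sets <- sets[keep]
  if (is.null(term_names)) term_names <- stats::setNames(names(sets), names(sets))
  structure(list(sets = sets, background = background,
                 term_names = term_names[names(sets)]),
            class = "annotation_map")
}

#' Read a GMT-style annotation file
#'
#' One term per line: term id, term name, then tab-separated member ids.
#' @param path GMT file.
#' @param background feature universe passed to [annotation_map()].
#' @return an `annotation_map`.
#' @export
read_gmt <- function(path, background) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) < 3)) stop("malformed GMT line: need id, name, members")
  ids <- vapply(parts, `[`, "", 1)
  nms <- vapply(parts, `[`, "", 2)
  sets <- stats::setNames(lapply(parts, function(x) x[-(1:2)]), ids)
  annotation_map(sets, background, stats::setNames(nms, ids))
}

#' Over-representation test of a selected feature set against term sets
#'
#' For each term with K background members, the probability that a random
#' draw of |top set| features from the N-feature background contains at least
#' the observed number of term members is the one-sided hypergeometric tail
#' `P(X >= significant)` — the one-sided Fisher exact test for enrichment.
#' `expected = K * |top set| / N`. Rows are sorted by p and carry
#' Benjamini-Hochberg adjusted values ([bh_adjust()]); the conventional
#' significance call is FDR < 0.05.
#'
#' @param top_set character vector of selected features, a subset of the
#'   map's background.
#' @param map an [annotation_map()].
#' @return data frame of class `enrichment_table`: `term`, `name`,
#'   `annotated`, `significant`, `expected`, `p`, `fdr`.
#' @export
fisher_enrichment <- function(top_set, map) {
  top_set <- unique(as.character(top_set))
  if (!all(top_set %in% map$background))
    stop("top_set members missing from the background: ",
         paste(utils::head(setdiff(top_set, map$background), 5), collapse = ", "))
  N <- length(map$background)
  n <- length(top_set)
  rows <- lapply(names(map$sets), function(id) {
    members <- map$sets[[id]]
    K <- length(members)
    sig <- length(intersect(top_set, members))
    data.frame(term = id, name = unname(map$term_names[id]), annotated = K,
               significant = sig, expected = K * n / N,
               p = stats::phyper(sig - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$term), ]
  out$fdr <- bh_adjust(out$p)
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up procedure with monotonicity enforcement (wraps
#' `stats::p.adjust(method = "BH")`).
#' @param p_values numeric vector of p-values in (0, 1\].
#' @return adjusted values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
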