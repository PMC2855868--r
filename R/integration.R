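# Bipartite gene-phenotype integration.
#
# Every candidate list (positional candidates of a QTL, or expression
# correlates of a trait in one tissue) becomes a phenotype vertex; genes are
# the other vertex class; an edge records membership. Gene degree measures
# how broadly a gene associates across the phenome, and the most-connected
# slice is tested for pathway over-representation with a one-sided
# hypergeometric test.

#' Build the bipartite gene-phenotype graph
#'
#' @param lists Named list; each element a character vector of gene ids (a
#'   candidate or correlate list). Duplicate genes within a list collapse to
#'   one edge.
#' @return List of class \code{"bipartite_graph"}: \code{edges} (data frame
#'   \code{gene}, \code{phenotype}), \code{genes}, \code{phenotypes}.
#' @export
build_bipartite <- function(lists) {
  if (length(lists) == 0) stop("empty list collection")
  if (is.null(names(lists)) || any(names(lists) == ""))
    names(lists) <- sprintf("list%03d", seq_along(lists))
  edges <- do.call(rbind, lapply(names(lists), function(nm) {
    g <- unique(lists[[nm]])
    if (length(g) == 0) return(NULL)
    data.frame(gene = g, phenotype = nm, stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) edges <- data.frame(gene = character(),
                                          phenotype = character())
  structure(list(edges = edges, genes = sort(unique(edges$gene)),
                 phenotypes = names(lists)),
            class = "bipartite_graph")
}

#' Rank genes by phenotype connectivity
#'
#' Genes sorted by degree (number of phenotype lists containing them)
#' descending, ties broken by gene id for a stable order. Singleton genes
#' can be eliminated (convergence filter).
#'
#' @param graph A \code{bipartite_graph}.
#' @param min_degree Keep genes with degree >= this (default 1 keeps all).
#' @return Data frame: \code{gene}, \code{degree}, sorted.
#' @export
connectivity_ranking <- function(graph, min_degree = 1L) {
  stopifnot(nrow(graph$edges) > 0)
  deg <- table(graph$edges$gene)
  out <- data.frame(gene = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[out$degree >= min_degree, , drop = FALSE]
  out <- out[order(-out$degree, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top slice of the connectivity ranking
#'
#' @param ranking Output of \code{\link{connectivity_ranking}}.
#' @param fraction Slice fraction (e.g. 0.05 or 0.10); slice size is
#'   \code{ceiling(fraction * nrow(ranking))}. Ties at the cut are included
#'   only up to the slice size, in the ranking's deterministic order.
#' @return Character vector of gene ids.
#' @export
top_slice <- function(ranking, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  k <- ceiling(fraction * nrow(ranking))
  ranking$gene[seq_len(k)]
}

#' Hypergeometric over-representation of gene sets in a slice
#'
#' For each set, p = P(X >= k) where X is hypergeometric with population
#' size N = |universe|, K = |set intersect universe| successes, and n =
#' |slice| draws.
#'
#' @param slice Character vector of gene ids (subset of universe).
#' @param sets Named list of gene-id vectors (GMT semantics).
#' @param universe All gene ids under consideration.
#' @param adjust Add a Benjamini-Hochberg adjusted-p column.
#' @return Data frame: \code{set}, \code{K}, \code{n}, \code{k}, \code{p}
#'   (and \code{p_adj}), one row per set, input order.
#' @export
hypergeometric_enrichment <- function(slice, sets, universe, adjust = TRUE) {
  if (length(universe) == 0) stop("empty universe")
  slice <- unique(slice)
  if (!all(slice %in% universe)) stop("slice contains genes outside the universe")
  N <- length(unique(universe))
  n <- length(slice)
  rows <- lapply(names(sets), function(nm) {
    set_u <- intersect(unique(sets[[nm]]), universe)
    K <- length(set_u)
    k <- length(intersect(slice, set_u))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, K = K, n = n, k = k, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
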