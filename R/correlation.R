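# Genetic correlation of strain means: trait vs trait (inter-laboratory
# comparisons, factor-score vs trait) and trait vs transcript abundance, with
# raw-threshold candidate list generation.

#' Correlate two strain-indexed vectors
#'
#' Pearson correlation on the strains shared by both vectors (inner join on
#' names), with a two-sided p-value from the t transform on n - 2 df.
#'
#' @param x,y Named numeric vectors (names = strain ids; NA entries dropped).
#' @param method \code{"pearson"} (default, the GeneNetwork convention) or
#'   \code{"spearman"}.
#' @return List: \code{r}, \code{p}, \code{n}, \code{defined} (FALSE when a
#'   vector is constant on the shared strains).
#' @export
correlate_strain_means <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  common <- intersect(names(x)[!is.na(x)], names(y)[!is.na(y)])
  n <- length(common)
  if (n < 3) stop("fewer than 3 shared strains")
  xv <- x[common]; yv <- y[common]
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, defined = FALSE))
  if (method == "spearman") { xv <- rank(xv); yv <- rank(yv) }
  r <- stats::cor(xv, yv)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
  list(r = r, p = min(p, 1), n = n, defined = TRUE)
}

#' Expression correlates of a trait
#'
#' Correlates a trait's strain means against every probe of an expression
#' matrix; probes passing the raw p threshold are collapsed to genes, keeping
#' the probe with the largest |r| per gene. No multiplicity correction is
#' applied at this stage (candidate lists are filtered downstream by
#' convergence across analyses).
#'
#' @param trait_means Named numeric vector of strain means.
#' @param expr An \code{expr_matrix}.
#' @param p_threshold Raw correlation p-value cutoff (default 0.001).
#' @param method Correlation method.
#' @return Data frame of class \code{"correlate_list"}: \code{gene_id},
#'   \code{probe_id}, \code{r}, \code{p}, \code{n}, sorted by |r| descending;
#'   attribute \code{tissue}.
#' @export
expression_correlates <- function(trait_means, expr, p_threshold = 0.001,
                                  method = "pearson") {
  common <- intersect(names(trait_means)[!is.na(trait_means)],
                      colnames(expr$values))
  n <- length(common)
  if (n < 3) stop("fewer than 3 strains shared with the expression matrix")
  if (n < 10) warning("fewer than 10 shared strains; correlations unstable")
  if (nrow(expr$values) == 0) {
    out <- data.frame(gene_id = character(), probe_id = character(),
                      r = numeric(), p = numeric(), n = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "tissue") <- expr$tissue
    class(out) <- c("correlate_list", "data.frame")
    return(out)
  }
  y <- trait_means[common]
  if (method == "spearman") {
    y <- rank(y)
    E <- t(apply(expr$values[, common, drop = FALSE], 1, rank))
  } else {
    E <- expr$values[, common, drop = FALSE]
  }
  ys <- (y - mean(y)) / stats::sd(y)
  Es <- t(scale(t(E)))
  Es[is.na(Es)] <- 0
  r <- as.vector(Es %*% ys) / (n - 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- pmin(2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE), 1)
  pass <- which(p < p_threshold)
  out <- data.frame(gene_id = expr$probes$gene_id[pass],
                    probe_id = expr$probes$probe_id[pass],
                    r = r[pass], p = p[pass], n = n,
                    stringsAsFactors = FALSE)
  # collapse probes to genes by max |r|
  out <- out[order(-abs(out$r)), , drop = FALSE]
  out <- out[!duplicated(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tissue") <- expr$tissue
  class(out) <- c("correlate_list", "data.frame")
  out
}
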