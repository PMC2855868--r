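# Multivariate extreme-strain detection.
#
# On a chosen set of correlated traits, the squared Mahalanobis distance of a
# strain's mean vector from the panel centroid follows (under multivariate
# normality) a chi-square with df equal to the number of traits; strains with
# upper-tail p below alpha are flagged as multivariate outliers.

#' Mahalanobis-distance outlier report
#'
#' The mean and covariance are estimated from all complete strains (including
#' the candidate; a leave-one-out variant is available). A singular
#' covariance falls back to the shrunk estimate unless \code{shrink} is
#' disabled. Per-trait standing labels each flagged strain high /
#' intermediate / low relative to panel tertiles.
#'
#' @param m Strain-by-trait numeric matrix restricted to the selected traits;
#'   strains with any missing value are dropped.
#' @param alpha Flagging threshold on the chi-square upper-tail p.
#' @param leave_one_out If \code{TRUE}, each strain's distance uses mean and
#'   covariance estimated without it.
#' @param shrink Allow fallback to the shrinkage covariance when the sample
#'   covariance is singular.
#' @return Data frame of class \code{"outlier_report"}: \code{strain},
#'   \code{D2}, \code{p}, \code{flagged}, plus one standing column per trait;
#'   attribute \code{"n_complete"}.
#' @export
mahalanobis_outliers <- function(m, alpha = 0.05, leave_one_out = FALSE,
                                 shrink = TRUE) {
  complete <- stats::complete.cases(m)
  x <- m[complete, , drop = FALSE]
  n <- nrow(x); p <- ncol(x)
  if (n < p + 2) stop("need at least #traits + 2 complete strains")

  d2_with <- function(xs, centre, S) {
    Si <- tryCatch(solve(S), error = function(e) NULL)
    if (is.null(Si)) {
      if (!shrink) stop("singular covariance and shrinkage disabled")
      shr <- shrink_correlation(xs)
      sds <- apply(xs, 2, stats::sd)
      S <- diag(sds) %*% shr$R %*% diag(sds)
      Si <- solve(S)
    }
    stats::mahalanobis(xs, centre, Si, inverted = TRUE)
  }

  if (!leave_one_out) {
    D2 <- d2_with(x, colMeans(x), stats::cov(x))
  } else {
    D2 <- vapply(seq_len(n), function(i) {
      xi <- x[-i, , drop = FALSE]
      d2_with(x[i, , drop = FALSE], colMeans(xi), stats::cov(xi))
    }, numeric(1))
  }
  pval <- stats::pchisq(D2, df = p, lower.tail = FALSE)
  out <- data.frame(strain = rownames(x), D2 = D2, p = pval,
                    flagged = pval < alpha, row.names = NULL,
                    stringsAsFactors = FALSE)
  for (tr in colnames(x)) {
    cuts <- stats::quantile(x[, tr], c(1, 2) / 3)
    out[[paste0("standing_", tr)]] <-
      c("low", "intermediate", "high")[findInterval(x[, tr], cuts) + 1L]
  }
  attr(out, "n_complete") <- n
  class(out) <- c("outlier_report", "data.frame")
  out
}
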