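# Storey q-value FDR estimation.
#
# pi0 (the null proportion) is estimated on a lambda grid with a cubic
# smoothing spline extrapolated to the largest lambda; q-values are then
# pi0-scaled Benjamini-Hochberg quantities, so forcing pi0 = 1 reproduces BH
# adjusted p-values exactly.

#' Storey pi0 estimate
#'
#' @param p P-values in [0, 1] (NA allowed, ignored).
#' @param lambda Tuning grid in [0, 1).
#' @return Estimated proportion of true nulls, in (0, 1].
#' @export
estimate_pi0 <- function(p, lambda = seq(0.05, 0.95, 0.05)) {
  p <- p[!is.na(p)]
  if (length(p) == 0) stop("no p-values supplied")
  stopifnot(all(p >= 0 & p <= 1))
  if (length(lambda) == 1) {
    pi0 <- mean(p > lambda) / (1 - lambda)
    return(min(max(pi0, .Machine$double.eps), 1))
  }
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  min(max(pi0, .Machine$double.eps), 1)
}

#' Storey q-values
#'
#' q_i is the minimum over p_j >= p_i of pi0 * m * p_j / rank(p_j): the
#' smallest estimated FDR at which test i would be called significant.
#'
#' @param p P-values (NA propagated).
#' @param pi0 Null proportion; \code{NULL} (default) estimates it via
#'   \code{\link{estimate_pi0}}, \code{1} gives Benjamini-Hochberg.
#' @param lambda Grid passed to \code{\link{estimate_pi0}}.
#' @return Q-values in the input order, monotone along sorted p.
#' @export
storey_qvalues <- function(p, pi0 = NULL, lambda = seq(0.05, 0.95, 0.05)) {
  if (length(p) == 0) stop("no p-values supplied")
  ok <- !is.na(p)
  if (!any(ok)) return(rep(NA_real_, length(p)))
  pv <- p[ok]
  stopifnot(all(pv >= 0 & pv <= 1))
  if (is.null(pi0)) {
    pi0 <- if (length(pv) >= 20) estimate_pi0(pv, lambda) else 1
  }
  m <- length(pv)
  o <- order(pv)
  q <- pi0 * m * pv[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- rep(NA_real_, length(p))
  out[ok][o] <- q
  out
}
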