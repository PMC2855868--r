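# Multi-trait latent factor pipeline for n < p strain-by-trait matrices:
# strain filtering by missingness, column-mean imputation, James-Stein-type
# shrinkage of the correlation matrix toward the identity (Schaefer-Strimmer
# analytic intensity), eigenvalue-based factor-count selection, unrotated
# maximum likelihood factor analysis by EM, and Thomson regression scores.

#' Drop strains with excessive missing data
#'
#' @param m Strain-by-trait numeric matrix with NAs.
#' @param max_missing_fraction Strains whose missing fraction strictly
#'   exceeds this are removed (default 0.25).
#' @return Filtered matrix; attribute \code{"removed"} holds a data frame of
#'   removed strains and their missing fractions.
#' @export
filter_strains <- function(m, max_missing_fraction = 0.25) {
  frac <- rowMeans(is.na(m))
  drop <- frac > max_missing_fraction
  if (all(drop)) stop("all strains exceed the missingness threshold")
  out <- m[!drop, , drop = FALSE]
  attr(out, "removed") <- data.frame(strain = rownames(m)[drop],
                                     missing_fraction = frac[drop],
                                     row.names = NULL,
                                     stringsAsFactors = FALSE)
  out
}

#' Column-mean imputation
#'
#' Missing cells are replaced by the trait's mean over observed strains,
#' leaving observed column means unchanged.
#'
#' @param m Strain-by-trait numeric matrix.
#' @return Complete matrix.
#' @export
impute_column_means <- function(m) {
  allmiss <- colSums(!is.na(m)) == 0
  if (any(allmiss))
    stop("trait(s) with no observed values: ",
         paste(colnames(m)[allmiss], collapse = ", "))
  mu <- colMeans(m, na.rm = TRUE)
  idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(idx)) m[idx] <- unname(mu[idx[, 2]])
  m
}

#' James-Stein-type shrinkage of the correlation matrix
#'
#' Shrinks off-diagonal sample correlations toward zero with the analytic
#' intensity lambda* = sum Var-hat(r_ij) / sum r_ij^2 (off-diagonal sums),
#' clipped to [0, 1]. The result (1 - lambda) R + lambda I is positive
#' definite whenever lambda* > 0, making it usable when traits outnumber
#' strains.
#'
#' @param m Strain-by-trait numeric matrix (complete).
#' @return List of class \code{"shrunk_correlation"}: \code{R} (p x p),
#'   \code{lambda}, \code{R_sample}.
#' @export
shrink_correlation <- function(m) {
  n <- nrow(m); p <- ncol(m)
  if (n < 3) stop("need at least 3 strains")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("constant trait column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  x <- scale(m)                       # unit-variance standardization (sd, n-1)
  w_bar <- crossprod(x) / n           # mean of w_kij = x_ki x_kj
  r <- n / (n - 1) * w_bar            # sample correlation
  # Var-hat(r_ij) = n/(n-1)^3 * sum_k (w_kij - w_bar_ij)^2
  sq <- crossprod(x^2) - n * w_bar^2  # sum_k w^2 - n w_bar^2
  v <- n / (n - 1)^3 * sq
  off <- upper.tri(r)
  denom <- sum(r[off]^2)
  lambda <- if (denom <= 0) 1 else min(max(sum(v[off]) / denom, 0), 1)
  R <- (1 - lambda) * r
  diag(R) <- 1
  structure(list(R = R, lambda = lambda, R_sample = r),
            class = "shrunk_correlation")
}

#' Number of factors by parallel analysis and optimal coordinates
#'
#' Parallel analysis: retain leading eigenvalues of the sample correlation
#' matrix that exceed the reference quantile of the corresponding eigenvalue
#' from random normal data of the same dimensions (the 95th percentile by
#' default; \code{quantile = 0.5} approximates Horn's mean criterion).
#' Optimal coordinates: retain eigenvalue i while it exceeds both the value
#' predicted at position i by the line through eigenvalues (i+1) and p, and
#' the parallel reference, stopping at the first failure.
#'
#' @param m Strain-by-trait numeric matrix (complete).
#' @param n_iter Random datasets for the reference distribution.
#' @param seed Seed for the random reference data.
#' @param quantile Reference quantile of the random eigenvalues.
#' @return List: \code{parallel_analysis}, \code{optimal_coordinates},
#'   \code{eigenvalues}, \code{reference}.
#' @export
select_n_factors <- function(m, n_iter = 100L, seed = 1L, quantile = 0.95) {
  n <- nrow(m); p <- ncol(m)
  if (p < 2)
    return(list(parallel_analysis = 0L, optimal_coordinates = 0L,
                eigenvalues = rep(1, p), reference = rep(1, p)))
  ev <- eigen(stats::cor(m), symmetric = TRUE, only.values = TRUE)$values
  set.seed(seed)
  rnd <- matrix(0, n_iter, p)
  for (i in seq_len(n_iter)) {
    rnd[i, ] <- eigen(stats::cor(matrix(stats::rnorm(n * p), n, p)),
                      symmetric = TRUE, only.values = TRUE)$values
  }
  ref <- apply(rnd, 2, stats::quantile, probs = quantile)
  pa <- 0L
  for (i in seq_len(p)) {
    if (ev[i] > ref[i]) pa <- i else break
  }
  oc <- 0L
  for (i in seq_len(p - 2)) {
    slope <- (ev[p] - ev[i + 1]) / (p - (i + 1))
    pred <- ev[i + 1] - slope
    if (ev[i] > pred && ev[i] > ref[i]) oc <- i else break
  }
  list(parallel_analysis = pa, optimal_coordinates = oc,
       eigenvalues = ev, reference = ref)
}

#' Unrotated maximum likelihood factor analysis by EM
#'
#' Fits the Gaussian factor model Sigma = Lambda Lambda' + Psi to a
#' correlation matrix by expectation-maximization, initialized from a
#' principal-axis decomposition with squared-multiple-correlation communality
#' estimates. No interpretive rotation (varimax etc.) is applied; the fit is
#' reported in the canonical maximum-likelihood orientation (loadings rotated
#' so that Lambda' Psi^-1 Lambda is diagonal, which identifies the otherwise
#' rotation-invariant solution). Factors are
#' ordered by variance explained (column sums of squared loadings / p) and
#' each column's sign is set so its largest-|loading| entry is positive.
#' Uniquenesses are floored at \code{psi_floor} (Heywood cases flagged).
#'
#' @param R A \code{shrunk_correlation} or a correlation matrix.
#' @param k Number of factors (k < p).
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood gain
#'   per observation falls below \code{tol} or after \code{max_iter}
#'   iterations.
#' @param psi_floor Lower bound on uniquenesses.
#' @return List of class \code{"factor_model"}: \code{loadings} (p x k),
#'   \code{uniquenesses}, \code{k}, \code{variance_explained},
#'   \code{cumulative_variance}, \code{loglik_trace} (per-observation scale,
#'   up to a constant), \code{converged}, \code{heywood}.
#' @export
ml_factor_analysis <- function(R, k, max_iter = 10000L, tol = 1e-10,
                               psi_floor = 1e-3) {
  S <- if (inherits(R, "shrunk_correlation")) R$R else R
  p <- ncol(S)
  stopifnot(k >= 1, k < p)
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("correlation matrix is not positive definite")
  # principal-axis init with SMC communalities: h_i^2 = 1 - 1/(R^-1)_ii
  smc <- 1 - 1 / diag(solve(S))
  ed <- eigen(S - diag(1 - smc), symmetric = TRUE)
  L <- ed$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(ed$values[seq_len(k)], 0)), k)
  psi <- pmax(diag(S) - rowSums(L^2), 0.05)

  neg_discrepancy <- function(L, psi) {
    Sg <- tcrossprod(L) + diag(psi, p)
    ch <- chol(Sg)
    ld <- 2 * sum(log(diag(ch)))
    -(ld + sum(diag(chol2inv(ch) %*% S))) / 2
  }
  ll <- neg_discrepancy(L, psi)
  trace <- ll
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Sg_inv <- chol2inv(chol(tcrossprod(L) + diag(psi, p)))
    B <- crossprod(L, Sg_inv)                      # k x p
    Ezz <- diag(k) - B %*% L + B %*% S %*% t(B)
    L_new <- S %*% t(B) %*% solve(Ezz)
    psi_new <- pmax(diag(S - L_new %*% B %*% S), psi_floor)
    L <- L_new; psi <- psi_new
    ll_new <- neg_discrepancy(L, psi)
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) < tol) { converged <- TRUE; ll <- ll_new; break }
    ll <- ll_new
  }
  heywood <- any(psi <= psi_floor + 1e-12)
  # the likelihood is invariant to orthogonal rotation of the factor space;
  # canonicalize to the standard ML representative with L' Psi^-1 L diagonal
  if (k > 1) {
    e <- eigen(crossprod(L, L / psi), symmetric = TRUE)
    L <- L %*% e$vectors
  }
  ve <- colSums(L^2) / p
  o <- order(ve, decreasing = TRUE)
  L <- L[, o, drop = FALSE]
  ve <- ve[o]
  for (j in seq_len(k)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  rownames(L) <- colnames(S)
  colnames(L) <- paste0("F", seq_len(k))
  structure(list(loadings = L, uniquenesses = stats::setNames(psi, colnames(S)),
                 k = k, variance_explained = ve,
                 cumulative_variance = cumsum(ve),
                 loglik_trace = trace, converged = converged,
                 heywood = heywood),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("ML factor model: %d factors on %d traits; %.1f%% variance%s\n",
              x$k, nrow(x$loadings), 100 * max(x$cumulative_variance),
              if (x$heywood) " (Heywood case floored)" else ""))
  invisible(x)
}

#' Thomson regression factor scores
#'
#' F = Z R^-1 Lambda, with Z the standardized strain-by-trait matrix and R
#' the (shrunk, hence invertible) correlation matrix the model was fitted on.
#'
#' @param Z Standardized strain-by-trait matrix.
#' @param model A \code{factor_model}.
#' @param R The \code{shrunk_correlation} (or correlation matrix) used in the
#'   fit.
#' @return Strains x k score matrix.
#' @export
factor_scores <- function(Z, model, R) {
  Rm <- if (inherits(R, "shrunk_correlation")) R$R else R
  sc <- Z %*% solve(Rm, model$loadings)
  colnames(sc) <- colnames(model$loadings)
  sc
}

#' Variance-explained report with a triviality floor
#'
#' @param model A \code{factor_model}.
#' @param variance_floor Factors explaining less than this fraction are
#'   flagged excluded from interpretation (default 0.013).
#' @return Data frame: \code{factor}, \code{variance}, \code{cumulative},
#'   \code{excluded}.
#' @export
variance_explained_report <- function(model, variance_floor = 0.013) {
  data.frame(factor = colnames(model$loadings),
             variance = model$variance_explained,
             cumulative = model$cumulative_variance,
             excluded = model$variance_explained < variance_floor,
             stringsAsFactors = FALSE)
}

#' Per-strain factor profiles (radar-plot data)
#'
#' @param scores Strains x factors score matrix.
#' @param first_k Number of leading factors to keep (default 8).
#' @return Long data frame: \code{strain}, \code{factor}, \code{score}.
#' @export
strain_profiles <- function(scores, first_k = 8L) {
  k <- min(first_k, ncol(scores))
  out <- expand.grid(strain = rownames(scores),
                     factor = colnames(scores)[seq_len(k)],
                     stringsAsFactors = FALSE)
  out$score <- scores[cbind(out$strain, out$factor)]
  out
}

#' Tucker congruence between best-matched loading columns
#'
#' Greedily matches columns of two loading matrices by |congruence| and
#' returns the per-match absolute congruence coefficients
#' |a'b| / (||a|| ||b||). Used as a rotation/sign-insensitive recovery
#' diagnostic.
#'
#' @param A,B Loading matrices with equal row counts.
#' @return Numeric vector, one coefficient per matched column pair.
#' @export
tucker_congruence <- function(A, B) {
  cc <- abs(crossprod(A, B)) /
    (sqrt(colSums(A^2)) %o% sqrt(colSums(B^2)))
  k <- min(ncol(A), ncol(B))
  out <- numeric(k)
  for (i in seq_len(k)) {
    m <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    out[i] <- cc[m[1], m[2]]
    cc[m[1], ] <- -Inf
    cc[, m[2]] <- -Inf
  }
  out
}

#' End-to-end factor pipeline on a strain-by-trait matrix
#'
#' Filter strains by missingness, impute column means, standardize, shrink
#' the correlation matrix, choose (or accept) the number of factors, fit the
#' unrotated ML factor model, and compute regression scores.
#'
#' @param m Strain-by-trait matrix with missing values allowed.
#' @param k Number of factors; \code{NULL} uses the parallel-analysis count.
#' @param max_missing_fraction Strain filter threshold.
#' @param variance_floor Interpretation floor for the variance report.
#' @param seed Seed for factor-count selection.
#' @return List of class \code{"factor_pipeline"}: \code{matrix} (filtered,
#'   imputed), \code{shrunk}, \code{selection}, \code{model}, \code{scores},
#'   \code{variance_report}, \code{removed_strains}.
#' @export
factor_pipeline <- function(m, k = NULL, max_missing_fraction = 0.25,
                            variance_floor = 0.013, seed = 1L) {
  filtered <- filter_strains(m, max_missing_fraction)
  removed <- attr(filtered, "removed")
  imp <- impute_column_means(filtered)
  shr <- shrink_correlation(imp)
  sel <- select_n_factors(imp, seed = seed)
  if (is.null(k)) k <- max(sel$parallel_analysis, 1L)
  model <- ml_factor_analysis(shr, k)
  Z <- scale(imp)
  scores <- factor_scores(Z, model, shr)
  rownames(scores) <- rownames(imp)
  structure(list(matrix = imp, shrunk = shr, selection = sel, model = model,
                 scores = scores,
                 variance_report = variance_explained_report(model, variance_floor),
                 removed_strains = removed),
            class = "factor_pipeline")
}
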