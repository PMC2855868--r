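# Factor pipeline: missingness filter, imputation, shrinkage, factor count,
# EM maximum-likelihood fit, scores.

make_missing_matrix <- function(n_strains, n_traits, miss_frac_per_strain) {
  m <- matrix(stats::rnorm(n_strains * n_traits), n_strains, n_traits,
              dimnames = list(sprintf("S%03d", seq_len(n_strains)),
                              sprintf("t%03d", seq_len(n_traits))))
  for (i in seq_len(n_strains)) {
    k <- round(miss_frac_per_strain[i] * n_traits)
    if (k > 0) m[i, seq_len(k)] <- NA
  }
  m
}

test_that("strain filter is strictly greater than 25%", {
  m <- make_missing_matrix(3, 100, c(0.26, 0.25, 0))
  f <- filter_strains(m)
  expect_setequal(rownames(f), c("S002", "S003"))
  expect_equal(attr(f, "removed")$strain, "S001")
  complete <- matrix(1, 3, 4, dimnames = list(paste0("S", 1:3), paste0("t", 1:4)))
  kept <- filter_strains(complete)
  expect_equal(kept, complete, ignore_attr = TRUE)  # complete: unchanged
  expect_equal(nrow(attr(kept, "removed")), 0)
})

test_that("a 95-strain panel with 32 heavy-missing strains retains 63", {
  frac <- c(rep(0.4, 32), rep(0.05, 63))
  m <- make_missing_matrix(95, 200, frac)
  f <- filter_strains(m)
  expect_equal(nrow(f), 63)
  expect_equal(nrow(attr(f, "removed")), 32)
})

test_that("column-mean imputation fills cells and preserves observed means", {
  m <- matrix(c(1, 2, NA, 4, 5, 6), 3, 2)
  colnames(m) <- c("a", "b")
  imp <- impute_column_means(m)
  expect_equal(unname(imp[3, 1]), 1.5)
  expect_equal(colMeans(imp), colMeans(m, na.rm = TRUE))
  m2 <- m; m2[, 2] <- NA
  expect_error(impute_column_means(m2), "b")
  expect_identical(impute_column_means(imp), imp)  # no missing: identity
})

test_that("shrinkage intensity matches the brute-force estimator", {
  set.seed(44)
  m <- matrix(stats::rnorm(5 * 20), 5, 20)
  shr <- shrink_correlation(m)
  # independent double-loop implementation of the analytic intensity
  n <- nrow(m)
  x <- scale(m)
  num <- 0; den <- 0
  for (i in 1:19) for (j in (i + 1):20) {
    w <- x[, i] * x[, j]
    wbar <- mean(w)
    num <- num + n / (n - 1)^3 * sum((w - wbar)^2)
    den <- den + (n / (n - 1) * wbar)^2
  }
  expect_equal(shr$lambda, min(num / den, 1), tolerance = 1e-10)
  ev <- eigen(shr$R, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)  # invertible even though n < p
  expect_equal(diag(shr$R), rep(1, 20))
  expect_true(isSymmetric(shr$R))
})

test_that("shrinkage vanishes for large n and saturates for orthogonal data", {
  set.seed(45)
  # fixed nonzero population correlation: estimation variance vanishes with n
  f <- stats::rnorm(2000)
  big <- matrix(stats::rnorm(2000 * 5), 2000, 5) + f
  expect_lt(shrink_correlation(big)$lambda, 0.05)
  orth <- unclass(stats::poly(1:12, 4))  # exactly uncorrelated columns
  expect_equal(shrink_correlation(orth)$lambda, 1)
  const <- cbind(a = rep(1, 10), b = stats::rnorm(10))
  expect_error(shrink_correlation(const), "constant")
})

test_that("factor-count criteria recover a planted 3-factor structure", {
  L <- matrix(0, 30, 3)
  L[1:10, 1] <- L[11:20, 2] <- L[21:30, 3] <- 0.8
  Psi <- diag(1 - rowSums(L^2))
  Sig <- L %*% t(L) + Psi
  ch <- chol(Sig)
  set.seed(46)
  ok <- vapply(1:30, function(i) {
    m <- matrix(stats::rnorm(100 * 30), 100, 30) %*% ch
    sel <- select_n_factors(m, n_iter = 30, seed = i)
    c(sel$parallel_analysis == 3, sel$optimal_coordinates == 3)
  }, logical(2))
  expect_gte(mean(ok[1, ]), 0.9)
  expect_gte(mean(ok[2, ]), 0.9)
})

test_that("null and degenerate inputs give at most one factor", {
  set.seed(47)
  ks <- vapply(1:40, function(i) {
    m <- matrix(stats::rnorm(50 * 10), 50, 10)
    sel <- select_n_factors(m, n_iter = 30, seed = 100 + i)
    max(sel$parallel_analysis, sel$optimal_coordinates)
  }, numeric(1))
  expect_gte(mean(ks <= 1), 0.95)
  expect_equal(select_n_factors(matrix(stats::rnorm(10), 10, 1))$parallel_analysis, 0)
})

test_that("EM factor analysis is exact on a constructed model", {
  L <- matrix(0, 10, 2)
  L[1:5, 1] <- c(0.9, 0.8, 0.7, 0.8, 0.9)
  L[6:10, 2] <- c(0.85, 0.75, 0.8, 0.9, 0.7)
  R <- L %*% t(L) + diag(1 - rowSums(L^2))
  fit <- ml_factor_analysis(R, 2)
  expect_gte(min(tucker_congruence(fit$loadings, L)), 0.99)
  # likelihood ascends monotonically
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  # communality + uniqueness reproduces the unit diagonal at convergence
  expect_equal(rowSums(fit$loadings^2) + unname(fit$uniquenesses),
               rep(1, 10), tolerance = 1e-4)
})

test_that("an identity correlation matrix fits as pure uniqueness", {
  fit <- ml_factor_analysis(diag(8), 2)
  expect_lt(max(abs(fit$loadings)), 1e-3)
  expect_equal(unname(fit$uniquenesses), rep(1, 8), tolerance = 1e-3)
  expect_lt(max(fit$variance_explained), 1e-6)
})

test_that("loadings agree with the reference ML implementation", {
  set.seed(48)
  L <- matrix(0, 12, 2)
  L[1:6, 1] <- 0.8; L[7:12, 2] <- 0.7
  ch <- chol(L %*% t(L) + diag(1 - rowSums(L^2)))
  m <- matrix(stats::rnorm(300 * 12), 300, 12) %*% ch
  R <- stats::cor(m)
  fit <- ml_factor_analysis(R, 2)
  ref <- stats::factanal(covmat = R, factors = 2, rotation = "none",
                         n.obs = 300)
  expect_gte(min(tucker_congruence(fit$loadings,
                                   matrix(ref$loadings, 12, 2))), 0.98)
})

test_that("factor scores recover simulated latent factors", {
  # trivial case: single unit loading on trait 1 under identity correlation
  model <- structure(list(loadings = matrix(c(1, rep(0, 4)), 5, 1),
                          uniquenesses = rep(1, 5), k = 1),
                     class = "factor_model")
  Z <- matrix(stats::rnorm(20 * 5), 20, 5)
  sc <- factor_scores(Z, model, diag(5))
  expect_equal(sc[, 1], Z[, 1])
  expect_equal(factor_scores(matrix(0, 1, 5), model, diag(5))[1, 1], 0)
  # simulation: 3 factors of distinct strength (equal-strength factors are
  # rotationally unidentified in the unrotated ML solution), 200 strains
  set.seed(49)
  p <- 30
  L <- matrix(0, p, 3)
  L[1:14, 1] <- 0.9
  L[15:24, 2] <- 0.85
  L[25:30, 3] <- 0.8
  F_true <- matrix(stats::rnorm(200 * 3), 200, 3)
  E <- matrix(stats::rnorm(200 * p), 200, p) %*% diag(sqrt(1 - rowSums(L^2)))
  X <- F_true %*% t(L) + E
  shr <- shrink_correlation(X)
  fit <- ml_factor_analysis(shr, 3)
  sc <- factor_scores(scale(X), fit, shr)
  best <- apply(abs(stats::cor(F_true, sc)), 1, max)
  expect_true(all(best > 0.9))
})

test_that("variance report applies the 1.3% interpretation floor", {
  ve <- c(0.4, 0.2, 0.012)
  model <- structure(list(loadings = matrix(0, 5, 3,
                                            dimnames = list(NULL, paste0("F", 1:3))),
                          variance_explained = ve,
                          cumulative_variance = cumsum(ve)),
                     class = "factor_model")
  rep <- variance_explained_report(model)
  expect_equal(rep$excluded, c(FALSE, FALSE, TRUE))
  expect_true(all(diff(rep$cumulative) >= 0))
})

test_that("the pipeline is deterministic and hands scores to QTL mapping", {
  cfg <- sim_config(n_strains_per_subpop = c(only = 50),
                    n_mice_per_sex_per_strain = c(4L, 4L),
                    n_chromosomes = 3L, markers_per_chromosome = 15L,
                    traits = data.frame(
                      trait_id = sprintf("t%02d", 1:10), battery = "b",
                      v_strain = 0.05, v_sex = 0, v_interaction = 0,
                      v_error = 0.95),
                    qtl_spec = data.frame(marker = "m02_008",
                                          trait_id = sprintf("t%02d", 1:10),
                                          a = 0.8, sex_specific = FALSE),
                    private_locus_count = 0L, seed = 52)
  geno <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(geno, cfg)
  m <- strain_means(ph)
  r1 <- factor_pipeline(m, k = 2, seed = 9)
  r2 <- factor_pipeline(m, k = 2, seed = 9)
  expect_identical(r1$model$loadings, r2$model$loadings)
  expect_identical(r1$scores, r2$scores)
  # a factor built from 10 traits driven by one marker maps back to it
  y <- r1$scores[, 1]
  names(y) <- rownames(r1$scores)
  s <- hk_scan(y, geno, 0)
  peak <- s[which.max(s$LOD), ]
  true_cM <- geno$map$cM[geno$map$marker == "m02_008"]
  expect_equal(peak$chr, "2")
  expect_lte(abs(peak$cM - true_cM), 10)
})
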