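# Strain/sex GLM, variance components, heritability, effect sizes, strain
# means, outlier flags.

test_that("constant traits are flagged degenerate", {
  d <- make_pheno(rep(1, 12), rep(c("a", "b", "c"), 4),
                  rep(c("F", "M"), each = 6))
  r <- fit_strain_sex_glm(d, "t1")
  expect_true(r$degenerate)
  expect_equal(r$p_strain, 1)
})

test_that("a pure strain signal yields a tiny strain p and null sex p", {
  set.seed(101)
  d <- sim_pheno_grid(strain_eff = c(0, 10), n_per_sex = 5, sd_e = 1)
  r <- fit_strain_sex_glm(d, "t1")
  expect_lt(r$p_strain, 1e-6)
  expect_gt(r$p_sex, 0.001)  # no sex effect was simulated
})

test_that("one-sex traits return strain test only", {
  set.seed(5)
  d <- make_pheno(stats::rnorm(12), rep(c("a", "b", "c"), 4), rep("F", 12))
  r <- fit_strain_sex_glm(d, "t1")
  expect_false(is.na(r$p_strain))
  expect_true(is.na(r$p_sex))
  expect_true(is.na(r$p_interaction))
})

test_that("marginal F tests match the independent Type-III oracle", {
  library(car)
  set.seed(77)
  for (i in 1:50) {
    s <- sample(3:6, 1)
    d <- do.call(rbind, lapply(seq_len(s), function(j) {
      do.call(rbind, lapply(c("F", "M"), function(sx) {
        n <- sample(2:5, 1)
        make_pheno(stats::rnorm(n, mean = j + (sx == "M") * stats::runif(1)),
                   rep(paste0("s", j), n), rep(sx, n))
      }))
    }))
    d$animal_id <- as.character(seq_len(nrow(d)))
    r <- fit_strain_sex_glm(d, "t1")
    op <- options(contrasts = c("contr.sum", "contr.poly"))
    fit <- stats::lm(value ~ strain * sex, data = d)
    a <- car::Anova(fit, type = 3)
    options(op)
    expect_equal(r$p_strain, a["strain", "Pr(>F)"], tolerance = 1e-10)
    expect_equal(r$p_sex, a["sex", "Pr(>F)"], tolerance = 1e-10)
    expect_equal(r$p_interaction, a["strain:sex", "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("variance components match the expected-mean-squares oracle", {
  d <- make_pheno(c(0, 2, 4, 6, 8, 10), rep(c("a", "b", "c"), each = 2),
                  rep("F", 6))
  vc <- estimate_variance_components(d, "t1", "female", "anova")
  expect_equal(vc$sigma2_error, 2)      # MSW = 2
  expect_equal(vc$sigma2_strain, 15)    # (MSB - MSW)/n = (32 - 2)/2
  vcr <- estimate_variance_components(d, "t1", "female", "reml")
  expect_equal(vcr$sigma2_strain, 15, tolerance = 1e-4)
  expect_equal(vcr$sigma2_error, 2, tolerance = 1e-4)
})

test_that("ANOVA estimator agrees with EMS algebra on balanced designs", {
  set.seed(12)
  for (i in 1:10) {
    d <- sim_pheno_grid(stats::rnorm(8, sd = 2), n_per_sex = 3, sd_e = 1)
    df <- d[d$sex == "F", ]
    vc <- estimate_variance_components(df, "t1", "female", "anova")
    fit <- stats::aov(value ~ strain, df)
    ms <- summary(fit)[[1]][["Mean Sq"]]
    expect_equal(vc$sigma2_error, ms[2], tolerance = 1e-8)
    expect_equal(vc$sigma2_strain, max((ms[1] - ms[2]) / 3, 0), tolerance = 1e-8)
  }
})

test_that("null strain variance truncates to zero with a flag", {
  set.seed(30)
  d <- make_pheno(stats::rnorm(40), rep(letters[1:4], each = 10), rep("F", 40))
  reps <- replicate(20, {
    d$value <- stats::rnorm(40)
    estimate_variance_components(d, "t1", "female", "anova")$sigma2_strain
  })
  expect_true(any(reps == 0))
  expect_true(all(reps >= 0))
})

test_that("heritability follows the intra-class correlation with Searle SE", {
  vc0 <- structure(list(sigma2_strain = 0, sigma2_sex = 0,
                        sigma2_interaction = 0, sigma2_error = 2,
                        scope = "pooled", group_sizes = rep(4, 10)),
                   class = "variance_components")
  expect_equal(heritability(vc0)$h2, 0)
  vc1 <- vc0; vc1$sigma2_strain <- 3; vc1$sigma2_error <- 0
  h1 <- heritability(vc1)
  expect_equal(h1$h2, 1)
  expect_equal(h1$se, 0)
  vc2 <- vc0; vc2$sigma2_strain <- 15; vc2$sigma2_error <- 2
  expect_equal(heritability(vc2)$h2, 15 / 17)
  # unbalanced n0 per Searle
  vc3 <- vc2; vc3$group_sizes <- c(2, 4, 6)
  h3 <- heritability(vc3)
  N <- 12; s <- 3
  expect_equal(h3$n0, (N - sum(c(2, 4, 6)^2) / N) / (s - 1))
  t <- 15 / 17
  expect_equal(h3$se,
               sqrt(2 * (1 - t)^2 * (1 + (h3$n0 - 1) * t)^2 /
                      (h3$n0 * (h3$n0 - 1) * (s - 1))))
})

test_that("partial omega-squared are variance shares", {
  vc <- structure(list(sigma2_strain = 15, sigma2_sex = 5,
                       sigma2_interaction = 0, sigma2_error = 80),
                  class = "variance_components")
  expect_equal(unname(partial_omega2(vc)), c(0.15, 0.05, 0))
  vc2 <- structure(list(sigma2_strain = 3, sigma2_sex = 0,
                        sigma2_interaction = 0, sigma2_error = 0),
                   class = "variance_components")
  expect_equal(unname(partial_omega2(vc2)["strain"]), 1)
})

test_that("effect-size classes use the agreed boundaries", {
  expect_equal(classify_effect_size(c(0.45, 0.25, 0.10, 0.30, 0.05)),
               c("large", "intermediate", "small", "intermediate", "small"))
})

test_that("strain means follow the sex policy", {
  d <- make_pheno(c(2, 4), c("a", "a"), c("M", "F"))
  expect_equal(unname(strain_means(d, policy = "pooled-LS")[1, 1]), 3)
  # unbalanced: 3 males mean 2, 1 female value 4 -> LS 3.0, not 2.5
  d2 <- make_pheno(c(2, 2, 2, 4), rep("a", 4), c("M", "M", "M", "F"))
  expect_equal(unname(strain_means(d2, policy = "pooled-LS")[1, 1]), 3)
  expect_equal(unname(strain_means(d2, policy = "male")[1, 1]), 2)
  # balanced: LS equals arithmetic
  set.seed(3)
  d3 <- sim_pheno_grid(stats::rnorm(4), n_per_sex = 3)
  ls <- strain_means(d3, policy = "pooled-LS")
  ar <- tapply(d3$value, d3$strain, mean)
  expect_equal(unname(ls[, 1]), as.vector(ar[rownames(ls)]))
})

test_that("sex policy splits on either sex or interaction q", {
  expect_equal(sex_policy_decision(0.01, 0.5), "by_sex")
  expect_equal(sex_policy_decision(0.9, 0.9), "pooled")
  expect_equal(sex_policy_decision(0.2, 0.03), "by_sex")
  expect_equal(sex_policy_decision(NA, NA), "pooled")
})

test_that("univariate outliers flagged strictly beyond 5 SD and retained", {
  set.seed(8)
  v <- c(stats::rnorm(1000), 8)
  d <- make_pheno(v, rep(c("a", "b"), length.out = 1001),
                  rep("F", 1001))
  fl <- flag_univariate_outliers(d, "t1")
  z <- abs((v - mean(v)) / stats::sd(v))
  expect_setequal(fl$value, v[z > 5])
  expect_true(1001 %in% which(z > 5))
  # constant data: no flags
  dc <- make_pheno(rep(1, 10), rep(c("a", "b"), 5), rep("F", 10))
  expect_equal(nrow(flag_univariate_outliers(dc, "t1")), 0)
  # strict inequality at the boundary
  expect_equal(nrow(flag_univariate_outliers(d, "t1", n_sd = max(z))), 0)
})

test_that("effects_table assembles q-values and the sex policy per trait", {
  p <- small_panel(seed = 60, n_traits = 4)
  eff <- effects_table(p$pheno, method = "anova")
  expect_equal(nrow(eff), 4)
  expect_true(all(eff$q_strain >= 0 & eff$q_strain <= 1, na.rm = TRUE))
  expect_true(all(eff$sex_policy %in% c("pooled", "by_sex")))
  expect_true(all(eff$h2_pooled >= 0 & eff$h2_pooled <= 1, na.rm = TRUE))
})
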