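# Per-trait strain/sex analysis: marginal (Type-III style) F tests, variance
# components, intra-class-correlation heritability with an unbalanced-design
# standard error, partial omega-squared effect sizes, strain means (including
# least-squares means for pooled sexes), and univariate outlier flags.

trait_subset <- function(data, trait_id, scope = "pooled") {
  d <- data[data$trait_id == trait_id & !is.na(data$value), , drop = FALSE]
  if (scope == "female") d <- d[d$sex == "F", , drop = FALSE]
  if (scope == "male") d <- d[d$sex == "M", , drop = FALSE]
  d
}

rss_of <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  list(rss = sum(fit$residuals^2), rank = fit$rank)
}

#' Marginal strain/sex/interaction F tests for one trait
#'
#' Fits the two-way cell-means model value ~ strain + sex + strain:sex with
#' sum-to-zero contrasts and tests each term marginally (non-sequential sums
#' of squares: each effect adjusted for all others), the Type-III convention
#' for unbalanced data.
#'
#' @param data Long phenotype table (\code{strain}, \code{sex},
#'   \code{trait_id}, \code{value}).
#' @param trait_id Trait to test.
#' @return List with \code{p_strain}, \code{p_sex}, \code{p_interaction},
#'   matching F statistics and dfs, and a \code{degenerate} flag. Tests that
#'   cannot be formed (one sex observed, zero residual variance) are
#'   \code{NA}.
#' @export
fit_strain_sex_glm <- function(data, trait_id) {
  d <- trait_subset(data, trait_id)
  if (nrow(d) < 3 || length(unique(d$strain)) < 2)
    stop("need at least 2 strains with replicate animals")
  d$strain <- factor(d$strain)
  d$sex <- factor(d$sex)
  one_sex <- nlevels(droplevels(d$sex)) < 2
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))

  res <- list(F_strain = NA_real_, p_strain = NA_real_,
              F_sex = NA_real_, p_sex = NA_real_,
              F_interaction = NA_real_, p_interaction = NA_real_,
              df_residual = NA_integer_, degenerate = FALSE)

  # Type-III: drop each term's columns from the full sum-contrast model
  # matrix (dropping via formula would promote the interaction instead)
  marginal_test <- function(X, asgn, term) {
    f <- rss_of(d$value, X)
    r <- rss_of(d$value, X[, asgn != term, drop = FALSE])
    df1 <- f$rank - r$rank
    df2 <- nrow(d) - f$rank
    if (df1 < 1 || df2 < 1 || f$rss <= 0) return(c(NA_real_, NA_real_, df2))
    Fv <- ((r$rss - f$rss) / df1) / (f$rss / df2)
    c(Fv, stats::pf(Fv, df1, df2, lower.tail = FALSE), df2)
  }

  if (stats::var(d$value) == 0) {
    res$degenerate <- TRUE
    res$p_strain <- res$p_sex <- res$p_interaction <- 1
    return(res)
  }
  if (one_sex) {
    X <- stats::model.matrix(~strain, d)
    t <- marginal_test(X, attr(X, "assign"), 1)
    res$F_strain <- t[1]; res$p_strain <- t[2]; res$df_residual <- as.integer(t[3])
    return(res)
  }
  X <- stats::model.matrix(~strain * sex, d)
  asgn <- attr(X, "assign")
  ts <- marginal_test(X, asgn, 1)
  tx <- marginal_test(X, asgn, 2)
  ti <- marginal_test(X, asgn, 3)
  res$F_strain <- ts[1]; res$p_strain <- ts[2]
  res$F_sex <- tx[1]; res$p_sex <- tx[2]
  res$F_interaction <- ti[1]; res$p_interaction <- ti[2]
  res$df_residual <- as.integer(ts[3])
  res
}

#' Variance components for one trait
#'
#' Per-sex scopes fit the one-way random-strain model; the pooled scope treats
#' strain, sex and strain-by-sex as random, the convention of variance
#' component estimation on such designs. Two estimators are provided: REML
#' (default, via \code{lme4}) and the ANOVA method of moments
#' (expected-mean-squares; exact for balanced designs, with Searle's n0 used
#' for unbalanced one-way layouts). Negative ANOVA estimates are truncated at
#' zero and flagged.
#'
#' @param data Long phenotype table.
#' @param trait_id Trait.
#' @param scope \code{"pooled"}, \code{"female"} or \code{"male"}.
#' @param method \code{"reml"} or \code{"anova"}.
#' @return List of class \code{"variance_components"}: \code{sigma2_strain},
#'   \code{sigma2_sex}, \code{sigma2_interaction}, \code{sigma2_error},
#'   \code{truncated} flag, \code{group_sizes} (animals per strain in scope).
#' @export
estimate_variance_components <- function(data, trait_id,
                                         scope = c("pooled", "female", "male"),
                                         method = c("reml", "anova")) {
  scope <- match.arg(scope)
  method <- match.arg(method)
  d <- trait_subset(data, trait_id, scope)
  if (length(unique(d$strain)) < 2) stop("need at least 2 strains")
  d$strain <- factor(d$strain)
  one_way <- scope != "pooled" || length(unique(d$sex)) < 2
  truncated <- FALSE
  s2 <- c(strain = 0, sex = 0, interaction = 0, error = 0)

  if (method == "anova") {
    if (one_way) {
      ni <- as.vector(table(d$strain))
      N <- sum(ni); s <- length(ni)
      n0 <- (N - sum(ni^2) / N) / (s - 1)
      gm <- mean(d$value)
      mi <- tapply(d$value, d$strain, mean)
      ssb <- sum(ni * (mi - gm)^2)
      ssw <- sum((d$value - mi[d$strain])^2)
      msb <- ssb / (s - 1)
      msw <- ssw / (N - s)
      s2["error"] <- msw
      est <- (msb - msw) / n0
      if (est < 0) { est <- 0; truncated <- TRUE }
      s2["strain"] <- est
    } else {
      # two-way random EMS (balanced form; unbalanced uses mean cell size)
      d$sex <- factor(d$sex)
      a <- nlevels(d$strain); b <- nlevels(d$sex)
      n <- nrow(d) / (a * b)
      cm <- tapply(d$value, list(d$strain, d$sex), mean)
      gm <- mean(cm, na.rm = TRUE)
      am <- rowMeans(cm, na.rm = TRUE); bm <- colMeans(cm, na.rm = TRUE)
      ms_a <- b * n * sum((am - gm)^2) / (a - 1)
      ms_b <- a * n * sum((bm - gm)^2) / (b - 1)
      inter <- sweep(sweep(cm, 1, am), 2, bm) + gm
      ms_ab <- n * sum(inter^2, na.rm = TRUE) / ((a - 1) * (b - 1))
      cellfit <- cm[cbind(as.integer(d$strain), as.integer(d$sex))]
      ms_e <- sum((d$value - cellfit)^2) / (nrow(d) - a * b)
      s2["error"] <- ms_e
      est <- c(strain = (ms_a - ms_ab) / (b * n),
               sex = (ms_b - ms_ab) / (a * n),
               interaction = (ms_ab - ms_e) / n)
      if (any(est < 0)) truncated <- TRUE
      s2[c("strain", "sex", "interaction")] <- pmax(est, 0)
    }
  } else {
    form <- if (one_way) value ~ 1 + (1 | strain) else
      value ~ 1 + (1 | strain) + (1 | sex) + (1 | strain:sex)
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(form, data = d,
                 control = lme4::lmerControl(check.nlev.gtr.1 = "ignore",
                                             check.nobs.vs.nlev = "ignore",
                                             check.nobs.vs.nRE = "ignore"))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    s2["error"] <- vc$vcov[vc$grp == "Residual"]
    s2["strain"] <- ifelse(any(vc$grp == "strain"), vc$vcov[vc$grp == "strain"], 0)
    if (!one_way) {
      s2["sex"] <- vc$vcov[vc$grp == "sex"]
      s2["interaction"] <- vc$vcov[vc$grp == "strain:sex"]
    }
  }
  structure(list(sigma2_strain = unname(s2["strain"]),
                 sigma2_sex = unname(s2["sex"]),
                 sigma2_interaction = unname(s2["interaction"]),
                 sigma2_error = unname(s2["error"]),
                 truncated = truncated, method = method, scope = scope,
                 group_sizes = as.vector(table(d$strain))),
            class = "variance_components")
}

#' Heritability as the strain intra-class correlation
#'
#' h^2 = sigma2_strain / (sigma2_strain + sigma2_error), the proportion of
#' phenotypic variance attributable to between-strain differences: a proxy for
#' broad-sense heritability in an inbred panel. The standard error uses the
#' classical large-sample intra-class-correlation variance with Searle's
#' effective per-strain sample size n0 = (N - sum(n_i^2)/N) / (s - 1) for
#' unbalanced designs:
#' Var(t) = 2 (1-t)^2 [1 + (n0-1) t]^2 / [n0 (n0-1) (s-1)].
#'
#' @param vc A \code{variance_components} object.
#' @param group_sizes Animals per strain; defaults to those recorded in
#'   \code{vc}.
#' @return List of class \code{"heritability"}: \code{h2}, \code{se},
#'   \code{n0}, \code{s}, \code{N}, \code{scope}, \code{defined}.
#' @export
heritability <- function(vc, group_sizes = vc$group_sizes) {
  ni <- group_sizes
  s <- length(ni); N <- sum(ni)
  if (s < 2) stop("need at least 2 strains")
  n0 <- (N - sum(ni^2) / N) / (s - 1)
  tot <- vc$sigma2_strain + vc$sigma2_error
  if (tot <= 0) {
    return(structure(list(h2 = NA_real_, se = NA_real_, n0 = n0, s = s, N = N,
                          scope = vc$scope, defined = FALSE),
                     class = "heritability"))
  }
  t <- vc$sigma2_strain / tot
  v <- 2 * (1 - t)^2 * (1 + (n0 - 1) * t)^2 / (n0 * (n0 - 1) * (s - 1))
  structure(list(h2 = t, se = sqrt(max(v, 0)), n0 = n0, s = s, N = N,
                 scope = vc$scope, defined = TRUE),
            class = "heritability")
}

#' Partial omega-squared effect sizes from variance components
#'
#' Each effect's share of total phenotypic variance:
#' omega^2_effect = sigma2_effect / (sigma2_strain + sigma2_sex +
#' sigma2_interaction + sigma2_error).
#'
#' @param vc A \code{variance_components} object.
#' @return Named numeric vector (\code{strain}, \code{sex},
#'   \code{interaction}); \code{NA} if total variance is zero.
#' @export
partial_omega2 <- function(vc) {
  tot <- vc$sigma2_strain + vc$sigma2_sex + vc$sigma2_interaction + vc$sigma2_error
  if (tot <= 0) return(c(strain = NA_real_, sex = NA_real_, interaction = NA_real_))
  c(strain = vc$sigma2_strain, sex = vc$sigma2_sex,
    interaction = vc$sigma2_interaction) / tot
}

#' Classify a strain effect size
#'
#' Conventional bands for amenability to genetic mapping: large above 0.30,
#' intermediate in (0.10, 0.30], small at or below 0.10.
#'
#' @param omega2 Partial omega-squared in [0, 1].
#' @return \code{"large"}, \code{"intermediate"} or \code{"small"}.
#' @export
classify_effect_size <- function(omega2) {
  stopifnot(all(omega2 >= 0 & omega2 <= 1, na.rm = TRUE))
  out <- ifelse(omega2 > 0.30, "large",
                ifelse(omega2 > 0.10, "intermediate", "small"))
  out[is.na(omega2)] <- NA_character_
  out
}

#' Strain means under a sex policy
#'
#' Per-sex policies take arithmetic strain means within that sex. The pooled
#' policy takes least-squares means from the strain + sex + strain:sex model,
#' which reduce to the equal-weight average of the two sex-specific strain
#' means regardless of sex sample sizes.
#'
#' @param data Long phenotype table.
#' @param trait_ids Traits to include; default all present.
#' @param policy \code{"pooled-LS"}, \code{"female"} or \code{"male"}.
#' @return Numeric matrix, strains x traits; cells with no animals in scope
#'   are \code{NA}.
#' @export
strain_means <- function(data, trait_ids = NULL,
                         policy = c("pooled-LS", "female", "male")) {
  policy <- match.arg(policy)
  if (is.null(trait_ids)) trait_ids <- unique(data$trait_id)
  strains <- sort(unique(data$strain))
  out <- matrix(NA_real_, length(strains), length(trait_ids),
                dimnames = list(strains, trait_ids))
  d <- data[!is.na(data$value) & data$trait_id %in% trait_ids, , drop = FALSE]
  for (tr in trait_ids) {
    dt <- d[d$trait_id == tr, , drop = FALSE]
    if (policy == "pooled-LS") {
      mf <- tapply(dt$value[dt$sex == "F"], dt$strain[dt$sex == "F"], mean)
      mm <- tapply(dt$value[dt$sex == "M"], dt$strain[dt$sex == "M"], mean)
      out[, tr] <- unname((mf[strains] + mm[strains]) / 2)
    } else {
      sx <- if (policy == "female") "F" else "M"
      m <- tapply(dt$value[dt$sex == sx], dt$strain[dt$sex == sx], mean)
      out[, tr] <- unname(m[strains])
    }
  }
  out
}

#' Decide whether a trait is analyzed pooled or by sex
#'
#' Sexes are kept separate downstream when there is a trend toward a sex
#' difference or a sex-by-strain interaction, operationalized as a q-value
#' below the threshold on either test.
#'
#' @param q_sex,q_interaction FDR q-values for the sex and interaction tests.
#' @param threshold Decision threshold (default 0.05).
#' @return \code{"by_sex"} or \code{"pooled"} (vectorized).
#' @export
sex_policy_decision <- function(q_sex, q_interaction, threshold = 0.05) {
  by_sex <- (!is.na(q_sex) & q_sex < threshold) |
    (!is.na(q_interaction) & q_interaction < threshold)
  ifelse(by_sex, "by_sex", "pooled")
}

#' Flag extreme univariate outliers
#'
#' Values more than 5 standard deviations from the trait mean (mean and SD
#' over all animals measured for the trait) are flagged for quality review.
#' Flagged values are reported, not removed.
#'
#' @param data Long phenotype table.
#' @param trait_id Trait.
#' @param n_sd Flagging threshold in SD units (strictly greater than).
#' @return Data frame of flagged records with a \code{z} column (possibly
#'   zero rows).
#' @export
flag_univariate_outliers <- function(data, trait_id, n_sd = 5) {
  d <- trait_subset(data, trait_id)
  if (nrow(d) < 3) stop("need at least 3 observations")
  s <- stats::sd(d$value)
  if (s == 0) return(cbind(d[0, ], z = numeric(0)))
  z <- (d$value - mean(d$value)) / s
  flagged <- abs(z) > n_sd
  cbind(d[flagged, , drop = FALSE], z = z[flagged])
}

#' Expected false discoveries at a q-value threshold
#'
#' At FDR level q, a list of n discoveries is expected to contain about
#' q * n false positives.
#'
#' @param n_discoveries Number of tests called significant.
#' @param q FDR threshold.
#' @return Expected count (not rounded).
#' @export
expected_false_discoveries <- function(n_discoveries, q = 0.05) {
  stopifnot(q >= 0, q <= 1, n_discoveries >= 0)
  q * n_discoveries
}

#' Per-trait effects table
#'
#' Runs the strain/sex GLM, variance components, partial omega-squared,
#' effect-size class, per-scope heritability and FDR q-values for every trait,
#' then applies the sex-policy decision.
#'
#' @param data Long phenotype table.
#' @param method Variance-component estimator passed through.
#' @param q_threshold Sex-policy q threshold.
#' @return Data frame, one row per trait, with p/q-values for the three
#'   effects, omega-squared values, effect class, heritability (pooled and by
#'   sex, with SEs) and \code{sex_policy}.
#' @export
effects_table <- function(data, method = "reml", q_threshold = 0.05) {
  traits <- unique(data$trait_id)
  rows <- lapply(traits, function(tr) {
    gl <- fit_strain_sex_glm(data, tr)
    vc <- estimate_variance_components(data, tr, "pooled", method)
    om <- partial_omega2(vc)
    h <- lapply(c(pooled = "pooled", female = "female", male = "male"),
                function(sc) {
                  v <- try(estimate_variance_components(data, tr, sc, method),
                           silent = TRUE)
                  if (inherits(v, "try-error")) return(list(h2 = NA, se = NA))
                  heritability(v)
                })
    data.frame(trait_id = tr, battery = data$battery[match(tr, data$trait_id)],
               p_strain = gl$p_strain, p_sex = gl$p_sex,
               p_interaction = gl$p_interaction,
               omega2_strain = om["strain"], omega2_sex = om["sex"],
               omega2_interaction = om["interaction"],
               effect_class = classify_effect_size(om["strain"]),
               h2_pooled = h$pooled$h2, h2_pooled_se = h$pooled$se,
               h2_female = h$female$h2, h2_female_se = h$female$se,
               h2_male = h$male$h2, h2_male_se = h$male$se,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$q_strain <- storey_qvalues(out$p_strain)
  out$q_sex <- storey_qvalues(out$p_sex)
  out$q_interaction <- storey_qvalues(out$p_interaction)
  out$sex_policy <- sex_policy_decision(out$q_sex, out$q_interaction, q_threshold)
  out
}
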