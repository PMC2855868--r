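# Sub-population contrast on a strain-structured panel.
#
# Mice are replicates within strains, not independent units, so the global
# old-vs-new sub-population comparison uses the nested model
# y = subpop + strain(subpop) + error with the alternate F ratio
# MS_subpop / MS_strain(subpop): strain nested within sub-population is the
# error stratum, with (g - 1, s - g) degrees of freedom.

#' Nested sub-population F test for one trait
#'
#' @param data Long phenotype table.
#' @param trait_id Trait.
#' @param subpop Named character vector, sub-population label per strain.
#' @param weighted If \code{TRUE} (default), sums of squares are computed on
#'   strain means weighted by strain sample size (Henderson method I
#'   analogue); \code{FALSE} uses unweighted strain means.
#' @return List of class \code{"nested_test"}: \code{F}, \code{df_num}
#'   (g - 1), \code{df_den} (s - g), \code{p}, \code{group_means},
#'   \code{degenerate} flag.
#' @export
nested_subpop_test <- function(data, trait_id, subpop, weighted = TRUE) {
  d <- trait_subset(data, trait_id)
  d$subpop <- subpop[d$strain]
  if (anyNA(d$subpop)) stop("strains without a sub-population label")
  groups <- unique(d$subpop)
  g <- length(groups)
  if (g < 2) stop("need at least 2 sub-populations")
  ni <- tapply(d$value, d$strain, length)
  mi <- tapply(d$value, d$strain, mean)
  grp <- subpop[names(mi)]
  if (any(table(grp) < 2)) stop("each sub-population needs at least 2 strains")
  s <- length(mi)
  w <- if (weighted) as.vector(ni) else rep(1, s)

  gw <- tapply(w, grp, sum)
  gmean <- tapply(w * mi, grp, sum) / gw
  grand <- sum(w * mi) / sum(w)
  ss_sub <- sum(gw * (gmean - grand)^2)
  ss_strain <- sum(w * (mi - gmean[grp])^2)
  df_num <- g - 1
  df_den <- s - g
  ms_sub <- ss_sub / df_num
  ms_strain <- ss_strain / df_den

  if (ms_strain <= 0) {
    return(structure(list(trait_id = trait_id, F = NA_real_, df_num = df_num,
                          df_den = df_den, p = NA_real_,
                          group_means = gmean, degenerate = TRUE),
                     class = "nested_test"))
  }
  Fv <- ms_sub / ms_strain
  structure(list(trait_id = trait_id, F = Fv, df_num = df_num, df_den = df_den,
                 p = stats::pf(Fv, df_num, df_den, lower.tail = FALSE),
                 group_means = gmean, degenerate = FALSE),
            class = "nested_test")
}

#' Sub-population tests across all traits
#'
#' @param data Long phenotype table.
#' @param subpop Named character vector, label per strain.
#' @param weighted Passed to \code{\link{nested_subpop_test}}.
#' @return Data frame with one row per trait (F, dfs, p, q, group means).
#' @export
subpop_effects <- function(data, subpop, weighted = TRUE) {
  traits <- unique(data$trait_id)
  rows <- lapply(traits, function(tr) {
    r <- nested_subpop_test(data, tr, subpop, weighted)
    out <- data.frame(trait_id = tr, F = r$F, df_num = r$df_num,
                      df_den = r$df_den, p = r$p, stringsAsFactors = FALSE)
    for (g in names(r$group_means))
      out[[paste0("mean_", g)]] <- unname(r$group_means[g])
    out
  })
  out <- do.call(rbind, rows)
  out$q <- storey_qvalues(out$p)
  out
}
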