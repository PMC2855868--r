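# End-to-end driver: synthetic panel -> per-trait effects -> strain means ->
# sub-population tests -> QTL scans with permutation thresholds -> expression
# correlates -> factor pipeline -> factor QTL -> multivariate outliers ->
# bipartite integration -> pathway enrichment. Every output file carries a
# provenance header with the configuration hash and seed.

#' Pipeline configuration
#'
#' Bundles the synthetic-panel design with every analysis threshold the
#' pipeline uses.
#'
#' @param sim An \code{ri_sim_config}.
#' @param out_dir Output directory (created if needed).
#' @param q_threshold FDR threshold for effects and the sex policy.
#' @param correlate_p Raw p threshold for expression correlate lists.
#' @param n_perm Permutations for genome-wide thresholds (0 disables
#'   thresholds and candidate extraction).
#' @param alpha_significant,alpha_suggestive Genome-wide adjusted P criteria.
#' @param step_cM Pseudomarker spacing.
#' @param max_missing_fraction Strain filter for the factor pipeline.
#' @param variance_floor Factor interpretation floor.
#' @param outlier_alpha Multivariate outlier flagging level.
#' @param top_fractions Connectivity slices for enrichment.
#' @param qtl_traits Trait ids to scan individually; \code{NULL} scans the
#'   first trait of the catalogue.
#' @param outlier_traits Trait ids for the multivariate outlier analysis;
#'   \code{NULL} uses the first four.
#' @param n_factors Factors to fit; \code{NULL} uses parallel analysis.
#' @param seed Pipeline seed.
#' @return List of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(sim = sim_config(), out_dir = tempfile("riphenome_"),
                            q_threshold = 0.05, correlate_p = 0.001,
                            n_perm = 1000L, alpha_significant = 0.05,
                            alpha_suggestive = suggestive_genomewide_alpha(),
                            step_cM = 1, max_missing_fraction = 0.25,
                            variance_floor = 0.013, outlier_alpha = 0.05,
                            top_fractions = c(0.05, 0.10),
                            qtl_traits = NULL, outlier_traits = NULL,
                            n_factors = NULL, seed = sim$seed) {
  stopifnot(q_threshold > 0, q_threshold < 1, correlate_p > 0, correlate_p < 1,
            n_perm >= 0, alpha_significant < alpha_suggestive,
            max_missing_fraction >= 0, max_missing_fraction < 1,
            outlier_alpha > 0, outlier_alpha < 1,
            all(top_fractions > 0 & top_fractions <= 1))
  structure(as.list(environment()), class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config[setdiff(names(config), "out_dir")], f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline on a synthetic panel
#'
#' @param config A \code{pipeline_config}.
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  stamp <- sprintf("riphenome seed=%d config=%s", config$seed, hash)
  say <- function(...) if (!quiet) message("[riphenome] ", ...)
  outfile <- function(...) file.path(config$out_dir, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  write_tsv <- function(d, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", stamp), con)
    utils::write.table(d, con, sep = "\t", row.names = FALSE, quote = FALSE)
  }

  say("simulating panel")
  sim <- config$sim
  geno <- stage("simulate", simulate_genotypes(sim))
  pheno <- stage("simulate", simulate_phenotypes(geno, sim))
  pheno <- inject_missing(pheno, sim$missing_rate, seed = sim$seed + 2L)
  annot <- make_gene_annotation(geno$map)
  expr <- simulate_expression(geno, annot, seed = sim$seed + 3L)
  gsets <- make_genesets(annot, seed = sim$seed + 4L)
  write_geno(geno, outfile("panel.geno"), stamp)
  write_traits(pheno, outfile("traits.csv"), stamp)
  write_bed(annot, outfile("genes.bed"), stamp)
  write_gmt(gsets, outfile("genesets.gmt"))

  say("per-trait effects")
  eff <- stage("effects", effects_table(pheno, q_threshold = config$q_threshold))
  write_tsv(eff, outfile("effects.tsv"))

  say("strain means")
  means <- list(pooled = strain_means(pheno, policy = "pooled-LS"),
                female = strain_means(pheno, policy = "female"),
                male = strain_means(pheno, policy = "male"))
  write_strain_means(means$pooled, outfile("strain_means_pooled.tsv"), stamp)

  say("sub-population tests")
  sp <- stage("subpop", subpop_effects(pheno, geno$subpop))
  write_tsv(sp, outfile("subpop.tsv"))

  qtl_traits <- config$qtl_traits
  if (is.null(qtl_traits)) qtl_traits <- sim$traits$trait_id[1]
  scans <- list(); peaks <- list(); cand_lists <- list()
  for (tr in qtl_traits) {
    policy <- eff$sex_policy[eff$trait_id == tr]
    scopes <- if (length(policy) && policy == "by_sex") c("female", "male")
    else "pooled"
    for (sc in scopes) {
      y <- means[[sc]][, tr]
      say("QTL scan: ", tr, " (", sc, ")")
      scan <- stage("qtl", hk_scan(y, geno, config$step_cM))
      thr <- NULL
      if (config$n_perm > 0) {
        thr <- permutation_thresholds(y, geno, n_perm = config$n_perm,
                                      seed = config$seed + 10L,
                                      step_cM = config$step_cM,
                                      alpha_significant = config$alpha_significant,
                                      alpha_suggestive = config$alpha_suggestive)
      } else {
        warning("permutations disabled; thresholds and positional candidates skipped")
      }
      pk <- scan_peaks(scan, thr)
      key <- paste0(tr, "_", sc)
      scans[[key]] <- scan; peaks[[key]] <- pk
      write_tsv(as.data.frame(scan), outfile("scan_%s.tsv", key))
      if (!is.null(thr)) {
        for (i in seq_len(nrow(pk))) {
          genes <- positional_candidates(pk$chr[i], pk$ci_lo_Mb[i],
                                         pk$ci_hi_Mb[i], annot)
          cand_lists[[sprintf("%s_pos_chr%s", key, pk$chr[i])]] <- genes
        }
        jsonlite::write_json(list(provenance = stamp,
                                  thresholds = thr[c("suggestive", "significant")],
                                  peaks = pk),
                             outfile("peaks_%s.json", key), auto_unbox = TRUE,
                             digits = NA)
      }
    }
  }

  say("expression correlates")
  corr_lists <- list()
  for (tr in qtl_traits) {
    cl <- stage("correlate",
                expression_correlates(means$pooled[, tr], expr,
                                      p_threshold = config$correlate_p))
    corr_lists[[paste0(tr, "_", expr$tissue)]] <- cl$gene_id
    write_tsv(as.data.frame(cl), outfile("correlates_%s.tsv", tr))
  }

  say("factor pipeline")
  fp <- stage("factors",
              factor_pipeline(means$pooled, k = config$n_factors,
                              max_missing_fraction = config$max_missing_fraction,
                              variance_floor = config$variance_floor,
                              seed = config$seed + 20L))
  write_tsv(data.frame(trait = rownames(fp$model$loadings),
                  fp$model$loadings, check.names = FALSE),
            outfile("factor_loadings.tsv"))
  write_strain_means(fp$scores, outfile("factor_scores.tsv"), stamp)
  write_tsv(fp$variance_report, outfile("factor_variance.tsv"))
  jsonlite::write_json(list(provenance = stamp,
                            removed_strains = fp$removed_strains,
                            shrinkage_lambda = fp$shrunk$lambda,
                            selection = fp$selection[c("parallel_analysis",
                                                       "optimal_coordinates")]),
                       outfile("factor_report.json"), auto_unbox = TRUE,
                       digits = NA)

  say("factor QTL")
  factor_scans <- list()
  for (j in seq_len(min(fp$model$k, 3))) {
    y <- fp$scores[, j]
    names(y) <- rownames(fp$scores)
    factor_scans[[colnames(fp$scores)[j]]] <- hk_scan(y, geno, config$step_cM)
  }

  say("multivariate outliers")
  otr <- config$outlier_traits
  if (is.null(otr)) otr <- utils::head(colnames(means$pooled), 4)
  om <- means$pooled[, otr, drop = FALSE]
  outl <- stage("outliers", mahalanobis_outliers(om, alpha = config$outlier_alpha))
  write_tsv(as.data.frame(outl), outfile("outliers.tsv"))

  say("bipartite integration")
  all_lists <- c(cand_lists, corr_lists)
  all_lists <- all_lists[lengths(all_lists) > 0]
  integ <- NULL
  if (length(all_lists) > 0) {
    graph <- build_bipartite(all_lists)
    ranking <- connectivity_ranking(graph)
    enrich <- lapply(config$top_fractions, function(f)
      hypergeometric_enrichment(top_slice(ranking, f), gsets, annot$gene_id))
    names(enrich) <- paste0("top_", config$top_fractions * 100, "pct")
    for (nm in names(enrich))
      write_tsv(enrich[[nm]], outfile("enrichment_%s.tsv", nm))
    integ <- list(graph = graph, ranking = ranking, enrichment = enrich)
  } else {
    warning("no candidate or correlate lists; integration skipped")
  }

  files <- list.files(config$out_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("riphenome")),
    seed = config$seed, config_hash = hash,
    thresholds = list(q = config$q_threshold, correlate_p = config$correlate_p,
                      n_perm = config$n_perm,
                      alpha_significant = config$alpha_significant,
                      alpha_suggestive = config$alpha_suggestive,
                      missing_filter = config$max_missing_fraction,
                      variance_floor = config$variance_floor,
                      outlier_alpha = config$outlier_alpha,
                      top_fractions = config$top_fractions),
    outputs = stats::setNames(as.list(unname(tools::md5sum(files))),
                              basename(files))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: ", config$out_dir)
  invisible(list(genotypes = geno, phenotypes = pheno, annotation = annot,
                 expression = expr, genesets = gsets, effects = eff,
                 means = means, subpop = sp, scans = scans, peaks = peaks,
                 candidates = cand_lists, correlates = corr_lists,
                 factors = fp, factor_scans = factor_scans, outliers = outl,
                 integration = integ, manifest = manifest))
}
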