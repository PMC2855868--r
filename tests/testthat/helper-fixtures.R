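# Shared in-code fixtures for the test suite.

# Minimal genotype object built by hand (bypasses the simulator).
toy_geno <- function(calls, cM = NULL, chr = NULL, Mb = NULL, subpop = NULL) {
  strains <- rownames(calls)
  markers <- colnames(calls)
  if (is.null(cM)) cM <- seq(0, by = 10, length.out = length(markers))
  if (is.null(chr)) chr <- rep("1", length(markers))
  if (is.null(Mb)) Mb <- cM * 2
  if (is.null(subpop)) subpop <- stats::setNames(rep("a", length(strains)), strains)
  structure(list(
    calls = calls,
    map = data.frame(marker = markers, chr = chr, cM = cM, Mb = Mb,
                     stringsAsFactors = FALSE),
    strains = strains, subpop = subpop
  ), class = "geno_matrix")
}

# Long phenotype table from a strain x sex grid of values.
make_pheno <- function(values, strains, sexes, trait_id = "t1",
                       battery = "test") {
  data.frame(
    animal_id = paste0("a", seq_along(values)),
    strain = strains, sex = sexes, battery = battery, trait_id = trait_id,
    value = values, stringsAsFactors = FALSE
  )
}

# Phenotypes for s strains x n animals/sex with additive components:
# value = strain_eff + sex_eff + interaction + N(0, sd_e)
sim_pheno_grid <- function(strain_eff, n_per_sex = 4, sex_eff = 0,
                           sd_e = 1, trait_id = "t1") {
  s <- length(strain_eff)
  strains <- sprintf("S%02d", seq_len(s))
  grid <- expand.grid(strain = strains, sex = c("F", "M"),
                      rep = seq_len(n_per_sex), stringsAsFactors = FALSE)
  eff <- strain_eff[match(grid$strain, strains)] +
    ifelse(grid$sex == "M", sex_eff, -sex_eff)
  make_pheno(eff + stats::rnorm(nrow(grid), 0, sd_e),
             grid$strain, grid$sex, trait_id)
}

# Small simulated panel reused across tests.
small_panel <- function(seed = 42, n_traits = 6, qtl_spec = NULL,
                        v_strain = NULL) {
  traits <- NULL
  if (!is.null(v_strain)) {
    traits <- data.frame(
      trait_id = sprintf("trait%03d", seq_along(v_strain)),
      battery = "test", v_strain = v_strain, v_sex = 0, v_interaction = 0,
      v_error = 1 - v_strain, stringsAsFactors = FALSE
    )
  }
  cfg <- sim_config(
    n_strains_per_subpop = c(TaylorI = 12, Recent = 18),
    n_mice_per_sex_per_strain = c(4L, 4L),
    n_chromosomes = 4L, markers_per_chromosome = 15L,
    n_traits = n_traits, traits = traits, qtl_spec = qtl_spec,
    missing_rate = 0, private_locus_count = 2L, seed = seed
  )
  geno <- simulate_genotypes(cfg)
  list(config = cfg, geno = geno, pheno = simulate_phenotypes(geno, cfg))
}
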