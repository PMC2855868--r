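# Haley-Knott scans, pseudomarker dosages, permutation thresholds, support
# intervals, positional candidates and group-conditional marker effects.

test_that("pseudomarker dosage reduces to the typed genotype at r1 = 0", {
  expect_equal(ri_expected_genotype(1, 0, 0, 0.2), 1)
  expect_equal(ri_expected_genotype(0, 1, 0, 0.2), 0)
})

test_that("pseudomarker dosage matches the flank-class enumeration", {
  for (r in c(0.05, 0.1, 0.3)) {
    R <- ri_expansion(r)
    # both flanks B, symmetric: P(D) = R^2 / (R^2 + (1-R)^2)
    expect_equal(ri_expected_genotype(0, 0, r, r), R^2 / (R^2 + (1 - R)^2),
                 tolerance = 1e-12)
    expect_lt(ri_expected_genotype(0, 0, r, r), 0.5)
    # disagreeing flanks at the midpoint: symmetry forces 1/2
    expect_equal(ri_expected_genotype(0, 1, r, r), 0.5)
    # asymmetric enumeration over the two-step transition products
    r2 <- r / 2
    R2 <- ri_expansion(r2)
    num <- R * (1 - R2)            # B ->(rec) D ->(no rec) D, right flank D
    den <- num + (1 - R) * R2      # vs B -> B -> D
    expect_equal(ri_expected_genotype(0, 1, r, r2), num / den,
                 tolerance = 1e-12)
  }
  expect_error(ri_expected_genotype(0, 1, 0, 0), "disagree")
})

test_that("hk_scan reproduces the hand regression example and handles nulls", {
  calls <- matrix(c("B", "B", "D", "D"), 4, 1,
                  dimnames = list(paste0("S", 1:4), "m1"))
  g <- toy_geno(calls)
  y <- stats::setNames(c(1, 2, 3, 4), paste0("S", 1:4))
  s <- suppressWarnings(hk_scan(y, g, step_cM = 0))
  expect_equal(s$LOD, 2 * log10(5), tolerance = 1e-10)  # RSS0=5, RSS1=1
  # constant phenotype: LOD = 0 everywhere
  y0 <- stats::setNames(rep(2, 4), paste0("S", 1:4))
  expect_equal(suppressWarnings(hk_scan(y0, g, 0))$LOD, 0)
  # monomorphic locus: LOD = 0
  gm <- toy_geno(matrix("B", 4, 1, dimnames = list(paste0("S", 1:4), "m1")))
  expect_equal(suppressWarnings(hk_scan(y, gm, 0))$LOD, 0)
})

test_that("typed-marker LOD equals the full-vs-reduced RSS oracle", {
  set.seed(19)
  worst <- 0
  for (i in 1:50) {
    n <- sample(20:40, 1)
    strains <- sprintf("S%03d", seq_len(n))
    calls <- matrix(sample(c("B", "D"), n * 5, replace = TRUE), n, 5,
                    dimnames = list(strains, paste0("m", 1:5)))
    g <- toy_geno(calls)
    y <- stats::setNames(stats::rnorm(n), strains)
    s <- hk_scan(y, g, step_cM = 0)
    for (j in 1:5) {
      dose <- as.numeric(calls[, j] == "D")
      rss0 <- stats::deviance(stats::lm(y ~ 1))
      rss1 <- stats::deviance(stats::lm(y ~ dose))
      lod <- (n / 2) * log10(rss0 / rss1)
      worst <- max(worst, abs(s$LOD[j] - lod))
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("LOD is invariant to affine transformation of the phenotype", {
  set.seed(23)
  p <- small_panel(seed = 23)
  y <- strain_means(p$pheno)[, 1]
  s1 <- hk_scan(y, p$geno, 2)
  s2 <- hk_scan(3.7 * y - 11, p$geno, 2)
  expect_equal(s1$LOD, s2$LOD, tolerance = 1e-9)
})

test_that("pseudomarker grid preserves typed-marker LODs", {
  p <- small_panel(seed = 29)
  y <- strain_means(p$pheno)[, 2]
  s0 <- hk_scan(y, p$geno, 0)
  s1 <- hk_scan(y, p$geno, 1)
  typed <- s1[s1$typed, ]
  expect_equal(typed$LOD[match(s0$locus, typed$locus)], s0$LOD,
               tolerance = 1e-9)
})

test_that("a planted QTL is localized near its marker", {
  cfg <- sim_config(n_strains_per_subpop = c(only = 60),
                    n_mice_per_sex_per_strain = c(8L, 8L),
                    n_chromosomes = 5L, markers_per_chromosome = 20L,
                    traits = data.frame(trait_id = "t", battery = "b",
                                        v_strain = 0.25, v_sex = 0,
                                        v_interaction = 0, v_error = 0.75),
                    qtl_spec = data.frame(marker = "m03_010", trait_id = "t",
                                          a = 0.55, sex_specific = FALSE),
                    private_locus_count = 0L, seed = 31)
  geno <- simulate_genotypes(cfg)
  true_pos <- geno$map[geno$map$marker == "m03_010", ]
  hit <- vapply(1:100, function(i) {
    ph <- simulate_phenotypes(geno, cfg, seed = 4000 + i)
    y <- strain_means(ph, "t")[, 1]
    s <- hk_scan(y, geno, 0)
    pk <- s[which.max(s$LOD), ]
    pk$chr == true_pos$chr && abs(pk$cM - true_pos$cM) <= 10
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("permutation thresholds are reproducible and ordered", {
  p <- small_panel(seed = 37)
  y <- strain_means(p$pheno)[, 1]
  t1 <- permutation_thresholds(y, p$geno, n_perm = 150, seed = 5)
  t2 <- permutation_thresholds(y, p$geno, n_perm = 150, seed = 5)
  expect_identical(t1, t2)
  expect_lte(t1$suggestive, t1$significant)
})

test_that("one-LOD intervals interpolate and truncate correctly", {
  scan <- data.frame(locus = c("a", "b", "c"), chr = "1",
                     cM = c(0, 10, 20), Mb = c(0, 20, 40), typed = TRUE,
                     LOD = c(1, 4, 1))
  class(scan) <- c("qtl_scan", "data.frame")
  ci <- one_lod_interval(scan, "1", 10)
  expect_equal(ci$lo_cM, 20 / 3, tolerance = 1e-10)
  expect_equal(ci$hi_cM, 40 / 3, tolerance = 1e-10)
  # never drops by 1 on the right: truncate at chromosome end
  scan$LOD <- c(1, 4, 3.5)
  ci2 <- one_lod_interval(scan, "1", 10)
  expect_equal(ci2$hi_cM, 20)
  # flat top: outermost grid points of the top, then the drop-off
  scan2 <- data.frame(locus = letters[1:5], chr = "1", cM = seq(0, 40, 10),
                      Mb = seq(0, 80, 20), typed = TRUE,
                      LOD = c(0.5, 3, 3, 3, 0.5))
  class(scan2) <- c("qtl_scan", "data.frame")
  ci3 <- one_lod_interval(scan2, "1", 20)
  expect_lt(ci3$lo_cM, 10)
  expect_gt(ci3$hi_cM, 30)
})

test_that("positional candidates use half-open overlap", {
  map <- data.frame(marker = c("a", "b"), chr = "1", cM = c(0, 50),
                    Mb = c(0, 100), stringsAsFactors = FALSE)
  ann <- make_gene_annotation(map, 1)
  genes <- positional_candidates("1", 10.5, 14.5, ann)
  expect_equal(length(genes), 5)  # genes tiling [10,15)
  expect_setequal(genes, ann$gene_id[ann$start_Mb %in% 10:14])
  # gene straddling an interval edge is included
  expect_true("g1_0010" %in% positional_candidates("1", 9.5, 9.6, ann))
  expect_warning(positional_candidates("99", 0, 1, ann), "absent")
})

test_that("group-conditional marker effects expose sign flips", {
  set.seed(41)
  n <- 40
  strains <- sprintf("S%03d", 1:n)
  calls <- matrix(sample(c("B", "D"), n * 3, replace = TRUE), n, 3,
                  dimnames = list(strains, paste0("m", 1:3)))
  grp <- stats::setNames(rep(c("old", "new"), each = n / 2), strains)
  g <- toy_geno(calls, subpop = grp)
  dose <- 2 * (calls[, 2] == "D") - 1
  # B > D in the old group, D > B in the new group
  y <- stats::setNames(ifelse(grp == "old", -dose, dose) +
                         stats::rnorm(n, 0, 0.1), strains)
  eff <- marker_effect_by_group(y, g, "m2")
  old_gap <- eff$mean[eff$group == "old" & eff$allele == "B"] -
    eff$mean[eff$group == "old" & eff$allele == "D"]
  new_gap <- eff$mean[eff$group == "new" & eff$allele == "B"] -
    eff$mean[eff$group == "new" & eff$allele == "D"]
  expect_gt(old_gap, 0)
  expect_lt(new_gap, 0)
  # combined-panel LOD at the flipped marker below the within-group LODs
  lod_at <- function(sub) {
    s <- suppressWarnings(hk_scan(y[sub], g, 0))
    s$LOD[s$locus == "m2"]
  }
  expect_lt(lod_at(strains), min(lod_at(strains[grp == "old"]),
                                 lod_at(strains[grp == "new"])))
})
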