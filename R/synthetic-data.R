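# Synthetic recombinant-inbred panel generator.
#
# Strains are simulated directly at the RI-statistics level: each chromosome is
# a two-state (B/D) Markov chain over the marker grid with stationary allele
# probabilities 1/2 and adjacent-marker transition probability given by the
# sib-mating RI map expansion R = 4r/(1+6r) of the Haldane recombination
# fraction r. This reproduces the expected genotype statistics of a fully
# inbred RI panel without forward-in-time breeding.

#' Haldane recombination fraction from map distance
#'
#' @param d_cM Map distance in centiMorgans.
#' @return Recombination fraction in [0, 0.5).
#' @export
haldane_r <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

#' Sib-mating RI map expansion
#'
#' Probability that two adjacent loci differ between the two parental alleles
#' in a fully inbred sib-mated RI strain, R = 4r / (1 + 6r).
#'
#' @param r Single-generation recombination fraction in [0, 0.5].
#' @return Expanded RI recombination fraction in [0, 0.5].
#' @export
ri_expansion <- function(r) 4 * r / (1 + 6 * r)

#' Simulation configuration for a synthetic RI panel
#'
#' Encodes the design of the emulated study population: two sub-populations of
#' RI strains (an older and a more recent set), 3--11 mice per sex per strain,
#' a multi-battery trait catalogue whose strain variance fractions span
#' 0.05--0.7, and a small number of loci private to one sub-population.
#'
#' @param n_strains_per_subpop Named integer vector, strains per sub-population.
#'   Names are the sub-population labels; the first is treated as the older set
#'   in which private loci are fixed.
#' @param n_mice_per_sex_per_strain Integer range (length 2) from which each
#'   strain's per-sex sample size is drawn uniformly.
#' @param n_chromosomes,markers_per_chromosome,chrom_length_cM Genome layout.
#' @param mb_per_cM Physical-to-genetic scale used to lay out Mb positions.
#' @param traits Data frame with columns \code{trait_id}, \code{battery},
#'   \code{v_strain}, \code{v_sex}, \code{v_interaction}, \code{v_error}
#'   (fractions summing to 1 per trait). \code{NULL} builds a default
#'   catalogue via \code{n_traits}.
#' @param n_traits Number of traits in the default catalogue.
#' @param qtl_spec Data frame with columns \code{marker}, \code{trait_id},
#'   \code{a} (additive effect of the D allele, trait SD units) and
#'   \code{sex_specific} (logical; effect present in females only).
#' @param missing_rate Probability that an individual trait value is missing.
#' @param private_locus_count Markers fixed for the B allele in the older
#'   sub-population while segregating in the other.
#' @param seed Base random seed; all generators derive their streams from it.
#' @return A list of class \code{"ri_sim_config"}.
#' @export
sim_config <- function(n_strains_per_subpop = c(TaylorI = 32, Recent = 63),
                       n_mice_per_sex_per_strain = c(3L, 11L),
                       n_chromosomes = 20L,
                       markers_per_chromosome = 50L,
                       chrom_length_cM = 100,
                       mb_per_cM = 2,
                       traits = NULL,
                       n_traits = 250L,
                       qtl_spec = NULL,
                       missing_rate = 0.05,
                       private_locus_count = 10L,
                       seed = 1L) {
  if (any(n_strains_per_subpop < 1) || length(n_strains_per_subpop) < 1)
    stop("need at least one sub-population with at least one strain")
  if (is.null(names(n_strains_per_subpop)))
    names(n_strains_per_subpop) <- paste0("subpop", seq_along(n_strains_per_subpop))
  if (n_chromosomes < 1 || markers_per_chromosome < 1)
    stop("zero markers or zero chromosomes in configuration")
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must be in [0, 1]")
  if (is.null(traits)) {
    set.seed(seed + 211L)
    batteries <- c("general", "cocaine", "morphine", "ethanol", "pain", "anxiety")
    v_strain <- stats::runif(n_traits, 0.05, 0.7)
    v_sex <- stats::runif(n_traits, 0, 0.08)
    v_int <- stats::runif(n_traits, 0, 0.10)
    traits <- data.frame(
      trait_id = sprintf("trait%03d", seq_len(n_traits)),
      battery = rep_len(batteries, n_traits),
      v_strain = v_strain, v_sex = v_sex, v_interaction = v_int,
      v_error = 1 - v_strain - v_sex - v_int,
      stringsAsFactors = FALSE
    )
  }
  frac <- as.matrix(traits[, c("v_strain", "v_sex", "v_interaction", "v_error")])
  if (any(frac < 0) || any(abs(rowSums(frac) - 1) > 1e-8))
    stop("variance fractions must be non-negative and sum to 1 per trait")
  structure(list(
    n_strains_per_subpop = n_strains_per_subpop,
    n_mice_per_sex_per_strain = as.integer(n_mice_per_sex_per_strain),
    n_chromosomes = as.integer(n_chromosomes),
    markers_per_chromosome = as.integer(markers_per_chromosome),
    chrom_length_cM = chrom_length_cM,
    mb_per_cM = mb_per_cM,
    traits = traits,
    qtl_spec = qtl_spec,
    missing_rate = missing_rate,
    private_locus_count = as.integer(private_locus_count),
    seed = as.integer(seed)
  ), class = "ri_sim_config")
}

#' Build the marker map implied by a configuration
#'
#' Markers are evenly spaced along each chromosome; physical positions are a
#' linear rescaling of the genetic map.
#'
#' @param config An \code{ri_sim_config}.
#' @return Data frame with columns \code{marker}, \code{chr}, \code{cM},
#'   \code{Mb}, ordered by chromosome then position.
#' @export
marker_map <- function(config) {
  m <- config$markers_per_chromosome
  pos <- if (m == 1) 0 else seq(0, config$chrom_length_cM, length.out = m)
  maps <- lapply(seq_len(config$n_chromosomes), function(ch) {
    data.frame(
      marker = sprintf("m%02d_%03d", ch, seq_len(m)),
      chr = as.character(ch),
      cM = pos,
      Mb = pos * config$mb_per_cM,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, maps)
}

#' Simulate RI genotypes
#'
#' Each strain's genome is a realization of the marker-grid Markov chain with
#' RI-expanded transition probabilities; calls are fully inbred (B/D only).
#' Private loci are forced to B in the first (older) sub-population.
#'
#' @param config An \code{ri_sim_config}.
#' @param seed Seed; defaults to \code{config$seed}.
#' @return A \code{geno_matrix}: list with \code{calls} (strains x markers
#'   character matrix in B/D/H/U), \code{map}, \code{strains},
#'   \code{subpop} (named character vector).
#' @export
simulate_genotypes <- function(config, seed = config$seed) {
  map <- marker_map(config)
  n_strains <- sum(config$n_strains_per_subpop)
  if (n_strains < 1 || nrow(map) < 1)
    stop("zero markers or zero strains")
  set.seed(seed)
  subpop <- rep(names(config$n_strains_per_subpop), config$n_strains_per_subpop)
  strains <- sprintf("S%03d", seq_len(n_strains))
  names(subpop) <- strains

  g <- matrix(NA_integer_, n_strains, nrow(map),
              dimnames = list(strains, map$marker))
  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    g[, idx[1]] <- stats::rbinom(n_strains, 1L, 0.5)
    if (length(idx) > 1) {
      d <- diff(map$cM[idx])
      R <- ri_expansion(haldane_r(d))
      for (j in seq_along(d)) {
        flip <- stats::rbinom(n_strains, 1L, R[j])
        g[, idx[j + 1]] <- (g[, idx[j]] + flip) %% 2L
      }
    }
  }
  if (config$private_locus_count > 0) {
    private <- sort(sample.int(nrow(map), min(config$private_locus_count, nrow(map))))
    old <- subpop == names(config$n_strains_per_subpop)[1]
    g[old, private] <- 0L  # fixed for B in the older sub-population
  }
  calls <- matrix(c("B", "D")[g + 1L], n_strains, nrow(map),
                  dimnames = dimnames(g))
  structure(list(calls = calls, map = map, strains = strains, subpop = subpop),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("RI genotype matrix: %d strains x %d markers (%d chromosomes)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$map$chr))))
  cat("sub-populations:", paste(sprintf("%s=%d", names(table(x$subpop)),
                                        table(x$subpop)), collapse = ", "), "\n")
  invisible(x)
}

# numeric dosage of the D allele: B=0, D=1, H=0.5, U treated as uninformative
geno_dosage <- function(geno) {
  d <- matrix(NA_real_, nrow(geno$calls), ncol(geno$calls),
              dimnames = dimnames(geno$calls))
  d[geno$calls == "B"] <- 0
  d[geno$calls == "D"] <- 1
  d[geno$calls == "H"] <- 0.5
  d[geno$calls == "U"] <- 0.5
  d
}

#' Simulate individual-mouse phenotypes on a genotyped panel
#'
#' Trait values follow an additive QTL + random strain + sex + strain-by-sex
#' + residual model. Random components are scaled so their variances equal
#' the configured fractions (total non-QTL variance 1); QTL effects, coded
#' -1/+1 for B/D, add on top of the polygenic strain component.
#'
#' @param genotypes A \code{geno_matrix}.
#' @param config An \code{ri_sim_config} whose \code{traits} table defines the
#'   catalogue and variance fractions.
#' @param seed Seed; defaults to \code{config$seed + 1}.
#' @return Long-format data frame of class \code{c("ri_phenotypes",
#'   "data.frame")}: \code{animal_id}, \code{strain}, \code{sex},
#'   \code{battery}, \code{trait_id}, \code{value}.
#' @export
simulate_phenotypes <- function(genotypes, config, seed = config$seed + 1L) {
  traits <- config$traits
  frac <- as.matrix(traits[, c("v_strain", "v_sex", "v_interaction", "v_error")])
  if (any(frac < 0) || any(abs(rowSums(frac) - 1) > 1e-8))
    stop("variance fractions must be non-negative and sum to 1 per trait")
  qtl <- config$qtl_spec
  if (!is.null(qtl) && !all(qtl$marker %in% genotypes$map$marker))
    stop("qtl_spec markers absent from genotype map")
  set.seed(seed)

  strains <- genotypes$strains
  ns <- length(strains)
  rng <- config$n_mice_per_sex_per_strain
  n_per <- if (rng[1] == rng[2]) rep(rng[1], ns) else
    sample(seq(rng[1], rng[2]), ns, replace = TRUE)

  strain_rep <- rep(strains, times = 2 * n_per)
  sex_rep <- unlist(lapply(n_per, function(n) rep(c("F", "M"), each = n)))
  animal <- paste0(strain_rep, "_", sex_rep,
                   unlist(lapply(n_per, function(n) c(seq_len(n), seq_len(n)))))
  n_animals <- length(animal)
  sidx <- match(strain_rep, strains)
  sexM <- sex_rep == "M"

  dos <- geno_dosage(genotypes)  # strains x markers, 0/1
  out <- vector("list", nrow(traits))
  for (t in seq_len(nrow(traits))) {
    v <- frac[t, ]
    u_strain <- stats::rnorm(ns, 0, sqrt(v[1]))
    # fixed +/- sex contrast with realized variance v_sex under balance
    s_sex <- ifelse(sexM, 1, -1) * sqrt(v[2])
    u_int <- matrix(stats::rnorm(2 * ns, 0, sqrt(v[3])), ns, 2)
    e <- stats::rnorm(n_animals, 0, sqrt(v[4]))
    y <- u_strain[sidx] + s_sex + u_int[cbind(sidx, sexM + 1L)] + e
    if (!is.null(qtl)) {
      qt <- qtl[qtl$trait_id == traits$trait_id[t], , drop = FALSE]
      for (k in seq_len(nrow(qt))) {
        gm <- 2 * dos[, qt$marker[k]] - 1  # -1/+1 coding
        eff <- qt$a[k] * gm[sidx]
        if (isTRUE(qt$sex_specific[k])) eff <- eff * (!sexM)
        y <- y + eff
      }
    }
    out[[t]] <- data.frame(
      animal_id = animal, strain = strain_rep, sex = sex_rep,
      battery = traits$battery[t], trait_id = traits$trait_id[t],
      value = y, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("ri_phenotypes", "data.frame")
  res
}

#' Knock out entries at random (missing-at-random emulation)
#'
#' Works on either a long phenotype table (\code{value} set to \code{NA}) or a
#' strain-by-trait numeric matrix. Strains listed in \code{strain_dropout} get
#' 40\% of their entries removed, which pushes them over the 25\%-missing
#' strain filter downstream.
#'
#' @param x \code{ri_phenotypes} data frame or numeric matrix with strain rows.
#' @param rate Per-entry missingness probability in [0, 1].
#' @param strain_dropout Optional strain ids to degrade heavily.
#' @param dropout_rate Missingness rate applied to dropout strains.
#' @param seed Random seed.
#' @return Same type as \code{x}.
#' @export
inject_missing <- function(x, rate, strain_dropout = NULL, dropout_rate = 0.4,
                           seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  set.seed(seed)
  if (is.matrix(x)) {
    drop <- matrix(stats::runif(length(x)) < rate, nrow(x), ncol(x))
    if (!is.null(strain_dropout)) {
      i <- rownames(x) %in% strain_dropout
      drop[i, ] <- matrix(stats::runif(sum(i) * ncol(x)) < dropout_rate,
                          sum(i), ncol(x))
    }
    x[drop] <- NA_real_
    return(x)
  }
  drop <- stats::runif(nrow(x)) < rate
  if (!is.null(strain_dropout)) {
    i <- x$strain %in% strain_dropout
    drop[i] <- stats::runif(sum(i)) < dropout_rate
  }
  x$value[drop] <- NA_real_
  x
}

#' Tile the simulated genome with non-overlapping genes
#'
#' Genes are half-open [start, end) Mb intervals of fixed size covering each
#' chromosome from 0 to its last marker position.
#'
#' @param map Marker map data frame (\code{chr}, \code{Mb}).
#' @param gene_size_mb Gene size in Mb.
#' @return Data frame: \code{gene_id}, \code{chr}, \code{start_Mb},
#'   \code{end_Mb}.
#' @export
make_gene_annotation <- function(map, gene_size_mb = 1) {
  if (nrow(map) == 0) stop("empty marker map")
  out <- lapply(unique(map$chr), function(ch) {
    len <- max(map$Mb[map$chr == ch])
    starts <- seq(0, len - gene_size_mb, by = gene_size_mb)
    if (length(starts) == 0) return(NULL)
    data.frame(
      gene_id = sprintf("g%s_%04d", ch, seq_along(starts)),
      chr = ch, start_Mb = starts, end_Mb = starts + gene_size_mb,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate an expression matrix with plantable cis effects
#'
#' A configured fraction of probes are cis-driven: their strain expression is
#' \code{gamma} times the (-1/+1 coded) genotype at the marker nearest the
#' probe's gene, plus unit-SD noise. Remaining probes are pure noise. Planting
#' a trait QTL at the same marker makes the probe a guaranteed genetic
#' correlate of that trait.
#'
#' @param genotypes A \code{geno_matrix}.
#' @param annotation Gene annotation from \code{\link{make_gene_annotation}}.
#' @param n_probes Number of probes; genes are recycled if fewer.
#' @param cis_fraction Fraction of probes that are cis-driven.
#' @param gamma Cis effect size (expression SD units per allele).
#' @param tissue Tissue label.
#' @param seed Random seed.
#' @return List of class \code{"expr_matrix"}: \code{values} (probes x
#'   strains), \code{probes} (probe_id, gene_id, chr, marker, cis), and
#'   \code{tissue}.
#' @export
simulate_expression <- function(genotypes, annotation, n_probes = 1000L,
                                cis_fraction = 0.1, gamma = 1.5,
                                tissue = "whole brain", seed = 1L) {
  if (is.null(annotation) || nrow(annotation) == 0) stop("empty annotation")
  set.seed(seed)
  genes <- annotation[rep_len(seq_len(nrow(annotation)), n_probes), ]
  mid <- (genes$start_Mb + genes$end_Mb) / 2
  map <- genotypes$map
  nearest <- vapply(seq_len(n_probes), function(i) {
    j <- which(map$chr == genes$chr[i])
    j[which.min(abs(map$Mb[j] - mid[i]))]
  }, integer(1))
  marker <- map$marker[nearest]
  cis <- seq_len(n_probes) <= round(cis_fraction * n_probes)
  cis <- sample(cis)  # scatter cis probes over the genome
  dos <- geno_dosage(genotypes)
  ns <- length(genotypes$strains)
  values <- matrix(stats::rnorm(n_probes * ns), n_probes, ns,
                   dimnames = list(sprintf("p%05d", seq_len(n_probes)),
                                   genotypes$strains))
  if (any(cis)) {
    gmat <- t(2 * dos[, marker[cis], drop = FALSE] - 1)
    values[cis, ] <- values[cis, ] + gamma * gmat
  }
  probes <- data.frame(
    probe_id = rownames(values), gene_id = genes$gene_id, chr = genes$chr,
    marker = marker, cis = cis, stringsAsFactors = FALSE
  )
  structure(list(values = values, probes = probes, tissue = tissue),
            class = "expr_matrix")
}

#' Sample reproducible gene sets (GMT semantics)
#'
#' @param annotation Gene annotation table.
#' @param n_sets Number of sets.
#' @param sizes Range (length 2) of set sizes.
#' @param seed Random seed.
#' @return Named list of character vectors with a \code{"description"}
#'   attribute per set.
#' @export
make_genesets <- function(annotation, n_sets = 20L, sizes = c(10L, 50L),
                          seed = 1L) {
  if (is.null(annotation) || nrow(annotation) == 0) stop("empty annotation")
  set.seed(seed)
  genes <- annotation$gene_id
  sets <- lapply(seq_len(n_sets), function(i) {
    k <- sample(seq(sizes[1], sizes[2]), 1)
    sort(sample(genes, min(k, length(genes))))
  })
  names(sets) <- sprintf("pathway_%02d", seq_len(n_sets))
  attr(sets, "descriptions") <- sprintf("synthetic pathway %d", seq_len(n_sets))
  sets
}
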