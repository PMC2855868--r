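# Haley-Knott genome scans on RI strain means.
#
# At a typed marker the regression of strain means on genotype dosage gives
# LOD = (n/2) log10(RSS0/RSS1), which for a single regressor equals
# -(n/2) log10(1 - r^2). Between markers, pseudomarker dosages are the
# conditional expectation of the D allele given the flanking genotypes under
# the marker-to-marker Markov model with RI-expanded recombination fractions.
# Genome-wide suggestive/significant thresholds come from permuting strain
# labels and recording the null distribution of the genome-wide maximum LOD.

#' Genome-wide adjusted P for the suggestive criterion
#'
#' One expected false positive per genome scan corresponds to a genome-wide
#' adjusted P of 1 - exp(-1) (the probability that a Poisson(1) count is
#' nonzero), conventionally rounded to 0.63.
#'
#' @return 1 - exp(-1).
#' @export
suggestive_genomewide_alpha <- function() 1 - exp(-1)

ri_transition <- function(same, R) ifelse(same, 1 - R, R)

#' Expected pseudomarker dosage from flanking RI genotypes
#'
#' Conditional probability that an untyped position carries the D allele,
#' given flanking genotypes (D-allele dosages) and the single-generation
#' recombination fractions to each flank. Fractions are expanded to the RI
#' scale R = 4r/(1+6r) before conditioning; the genotype process along the
#' chromosome is treated as Markov.
#'
#' @param flank_left,flank_right D-allele dosage of the flanking genotypes
#'   (0 = B, 1 = D; 0.5 for uninformative). \code{NA} drops that flank.
#' @param r1,r2 Recombination fractions (single-generation scale) to the left
#'   and right flank, in [0, 0.5].
#' @return Probability of the D allele in [0, 1].
#' @export
ri_expected_genotype <- function(flank_left, flank_right, r1, r2) {
  stopifnot(all(c(r1, r2) >= 0), all(c(r1, r2) <= 0.5))
  R1 <- ri_expansion(r1)
  R2 <- ri_expansion(r2)
  if (!is.na(flank_left) && !is.na(flank_right) &&
      r1 == 0 && r2 == 0 && flank_left != flank_right)
    stop("flanking genotypes disagree at zero recombination distance")
  if (is.na(flank_left) && is.na(flank_right)) return(0.5)
  pD_left <- if (is.na(flank_left)) 0.5 else
    flank_left * (1 - R1) + (1 - flank_left) * R1
  if (is.na(flank_right)) return(pD_left)
  lik_D <- flank_right * (1 - R2) + (1 - flank_right) * R2
  lik_B <- flank_right * R2 + (1 - flank_right) * (1 - R2)
  num <- pD_left * lik_D
  den <- num + (1 - pD_left) * lik_B
  if (den == 0) stop("inconsistent flanking genotypes")
  num / den
}

#' Dosage matrix on a cM grid of markers and pseudomarkers
#'
#' @param genotypes A \code{geno_matrix}.
#' @param step_cM Pseudomarker spacing; \code{0} scans typed markers only.
#' @return List: \code{dosage} (strains x loci), \code{grid} data frame
#'   (\code{locus}, \code{chr}, \code{cM}, \code{Mb}, \code{typed}).
#' @export
dosage_grid <- function(genotypes, step_cM = 1) {
  map <- genotypes$map
  dos <- geno_dosage(genotypes)
  grids <- list(); mats <- list()
  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    cm <- map$cM[idx]
    mb <- map$Mb[idx]
    pos <- cm
    if (step_cM > 0 && length(idx) > 1) {
      pos <- sort(unique(c(cm, seq(min(cm), max(cm), by = step_cM))))
    }
    typed <- pos %in% cm
    D <- matrix(NA_real_, nrow(dos), length(pos))
    for (j in seq_along(pos)) {
      if (typed[j]) {
        D[, j] <- dos[, idx[match(pos[j], cm)]]
      } else {
        li <- max(which(cm < pos[j]))
        ri <- min(which(cm > pos[j]))
        r1 <- haldane_r(pos[j] - cm[li])
        r2 <- haldane_r(cm[ri] - pos[j])
        D[, j] <- vapply(seq_len(nrow(dos)), function(s)
          ri_expected_genotype(dos[s, idx[li]], dos[s, idx[ri]], r1, r2),
          numeric(1))
      }
    }
    mbpos <- if (length(unique(cm)) < 2) rep(mb[1], length(pos)) else
      stats::approx(cm, mb, xout = pos, rule = 2, ties = "ordered")$y
    grids[[ch]] <- data.frame(
      locus = ifelse(typed, map$marker[idx][match(pos, cm)],
                     sprintf("c%s_loc%.1f", ch, pos)),
      chr = ch, cM = pos, Mb = mbpos, typed = typed,
      stringsAsFactors = FALSE
    )
    mats[[ch]] <- D
  }
  grid <- do.call(rbind, grids)
  rownames(grid) <- NULL
  dosage <- do.call(cbind, mats)
  dimnames(dosage) <- list(rownames(dos), grid$locus)
  list(dosage = dosage, grid = grid)
}

# LOD profile(s): Y is n x T (traits in columns), D is n x L
scan_lod_matrix <- function(Y, D) {
  n <- nrow(Y)
  Ys <- scale(Y)
  Ds <- scale(D)
  Ys[is.na(Ys)] <- 0  # zero-variance trait -> LOD 0
  Ds[is.na(Ds)] <- 0  # monomorphic locus -> LOD 0
  r <- crossprod(Ds, Ys) / (n - 1)
  r2 <- pmin(r^2, 1 - 1e-12)
  -(n / 2) * log10(1 - r2)
}

#' Haley-Knott genome scan on strain means
#'
#' @param y Named numeric vector of strain means (names = strain ids).
#' @param genotypes A \code{geno_matrix}.
#' @param step_cM Pseudomarker spacing (default 1 cM).
#' @return Data frame of class \code{"qtl_scan"}: \code{locus}, \code{chr},
#'   \code{cM}, \code{Mb}, \code{typed}, \code{LOD}; attributes \code{n}
#'   (strains used) and \code{strains}.
#' @export
hk_scan <- function(y, genotypes, step_cM = 1) {
  common <- intersect(names(y)[!is.na(y)], genotypes$strains)
  if (length(common) < 2) stop("fewer than 2 strains shared between y and genotypes")
  if (length(common) < 10)
    warning("fewer than 10 strains in scan; LOD scores will be unstable")
  dg <- dosage_grid(genotypes, step_cM)
  D <- dg$dosage[common, , drop = FALSE]
  lod <- scan_lod_matrix(matrix(y[common], ncol = 1), D)
  out <- dg$grid
  out$LOD <- as.vector(lod)
  attr(out, "n") <- length(common)
  attr(out, "strains") <- common
  class(out) <- c("qtl_scan", "data.frame")
  out
}

#' Permutation thresholds for genome-wide significance
#'
#' Strain labels of y are permuted against the genotype rows (preserving the
#' marker correlation structure), the genome is rescanned, and the maximum
#' LOD per permutation is recorded. The significant and suggestive thresholds
#' are the 95th and 37th percentiles of this null distribution, i.e.
#' genome-wide adjusted P of 0.05 and 1 - exp(-1) ~ 0.63.
#'
#' @param y Named numeric vector of strain means.
#' @param genotypes A \code{geno_matrix}.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Random seed.
#' @param step_cM Pseudomarker spacing.
#' @param alpha_significant,alpha_suggestive Genome-wide adjusted P criteria.
#' @return List: \code{suggestive}, \code{significant}, \code{max_lods},
#'   \code{n_perm}.
#' @export
permutation_thresholds <- function(y, genotypes, n_perm = 1000, seed = 1L,
                                   step_cM = 1,
                                   alpha_significant = 0.05,
                                   alpha_suggestive = suggestive_genomewide_alpha()) {
  stopifnot(n_perm >= 100)
  common <- intersect(names(y)[!is.na(y)], genotypes$strains)
  dg <- dosage_grid(genotypes, step_cM)
  D <- dg$dosage[common, , drop = FALSE]
  yv <- y[common]
  set.seed(seed)
  Y <- vapply(seq_len(n_perm), function(i) sample(yv), numeric(length(yv)))
  lod <- scan_lod_matrix(Y, D)
  max_lods <- apply(lod, 2, max)
  list(suggestive = unname(stats::quantile(max_lods, 1 - alpha_suggestive)),
       significant = unname(stats::quantile(max_lods, 1 - alpha_significant)),
       max_lods = max_lods, n_perm = n_perm)
}

#' One-LOD support interval around a peak
#'
#' Walks outward from the peak to where the profile first falls one LOD unit
#' below the peak, linearly interpolating between grid points; truncates at
#' chromosome ends. Flat-topped peaks use the outermost grid points of the
#' top before applying the drop-off.
#'
#' @param scan A \code{qtl_scan}.
#' @param chr Chromosome of the peak.
#' @param peak_cM Peak position (must be a grid point).
#' @param drop LOD drop defining the interval (default 1).
#' @return List: \code{lo_cM}, \code{hi_cM}, \code{lo_Mb}, \code{hi_Mb},
#'   \code{peak_cM}, \code{peak_LOD}.
#' @export
one_lod_interval <- function(scan, chr, peak_cM, drop = 1) {
  s <- scan[scan$chr == chr, , drop = FALSE]
  s <- s[order(s$cM), , drop = FALSE]
  i <- which.min(abs(s$cM - peak_cM))
  peak_lod <- s$LOD[i]
  target <- peak_lod - drop
  tol <- 1e-9
  # flat top: outermost grid points holding the peak value
  lo_i <- i; while (lo_i > 1 && s$LOD[lo_i - 1] >= peak_lod - tol) lo_i <- lo_i - 1
  hi_i <- i; while (hi_i < nrow(s) && s$LOD[hi_i + 1] >= peak_lod - tol) hi_i <- hi_i + 1

  interp <- function(j1, j2) {
    # crossing of `target` between grid points j1 (above) and j2 (below)
    s$cM[j1] + (target - s$LOD[j1]) * (s$cM[j2] - s$cM[j1]) /
      (s$LOD[j2] - s$LOD[j1])
  }
  lo_cM <- s$cM[1]
  j <- lo_i
  while (j > 1) {
    if (s$LOD[j - 1] < target) { lo_cM <- interp(j, j - 1); break }
    j <- j - 1
  }
  hi_cM <- s$cM[nrow(s)]
  j <- hi_i
  while (j < nrow(s)) {
    if (s$LOD[j + 1] < target) { hi_cM <- interp(j, j + 1); break }
    j <- j + 1
  }
  to_mb <- function(x) stats::approx(s$cM, s$Mb, xout = x, rule = 2,
                                     ties = "ordered")$y
  list(lo_cM = lo_cM, hi_cM = hi_cM, lo_Mb = to_mb(lo_cM), hi_Mb = to_mb(hi_cM),
       peak_cM = s$cM[i], peak_LOD = peak_lod)
}

#' Peaks of a genome scan with classification and support intervals
#'
#' One peak per chromosome whose maximum exceeds the suggestive threshold;
#' ties at the maximum report the leftmost position with all co-peak
#' positions listed.
#'
#' @param scan A \code{qtl_scan}.
#' @param thresholds List with \code{suggestive} and \code{significant}
#'   (from \code{\link{permutation_thresholds}}), or \code{NULL} to report
#'   all per-chromosome maxima unclassified.
#' @param drop LOD drop for the support interval.
#' @return Data frame: \code{chr}, \code{peak_cM}, \code{peak_Mb},
#'   \code{peak_LOD}, \code{classification}, \code{ci_lo_cM}, \code{ci_hi_cM},
#'   \code{ci_lo_Mb}, \code{ci_hi_Mb}, \code{co_peaks}.
#' @export
scan_peaks <- function(scan, thresholds = NULL, drop = 1) {
  rows <- lapply(unique(scan$chr), function(ch) {
    s <- scan[scan$chr == ch, , drop = FALSE]
    s <- s[order(s$cM), , drop = FALSE]
    mx <- max(s$LOD)
    if (!is.null(thresholds) && mx < thresholds$suggestive) return(NULL)
    at <- which(abs(s$LOD - mx) < 1e-9)
    i <- at[1]  # leftmost on ties
    ci <- one_lod_interval(scan, ch, s$cM[i], drop)
    cls <- if (is.null(thresholds)) NA_character_
    else if (mx >= thresholds$significant) "significant" else "suggestive"
    data.frame(chr = ch, peak_cM = s$cM[i], peak_Mb = s$Mb[i], peak_LOD = mx,
               classification = cls, ci_lo_cM = ci$lo_cM, ci_hi_cM = ci$hi_cM,
               ci_lo_Mb = ci$lo_Mb, ci_hi_Mb = ci$hi_Mb,
               co_peaks = paste(s$cM[at], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chr = character(), peak_cM = numeric(), peak_Mb = numeric(),
                      peak_LOD = numeric(), classification = character(),
                      ci_lo_cM = numeric(), ci_hi_cM = numeric(),
                      ci_lo_Mb = numeric(), ci_hi_Mb = numeric(),
                      co_peaks = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Positional candidate genes under a support interval
#'
#' Genes whose half-open [start, end) Mb span overlaps the interval at all.
#'
#' @param chr Chromosome.
#' @param lo_Mb,hi_Mb Support interval in Mb.
#' @param annotation Gene annotation table (\code{gene_id}, \code{chr},
#'   \code{start_Mb}, \code{end_Mb}).
#' @return Character vector of gene ids (possibly empty, with a warning if
#'   the chromosome is absent from the annotation).
#' @export
positional_candidates <- function(chr, lo_Mb, hi_Mb, annotation) {
  a <- annotation[annotation$chr == chr, , drop = FALSE]
  if (nrow(a) == 0) {
    warning("chromosome ", chr, " absent from annotation")
    return(character(0))
  }
  a$gene_id[a$start_Mb < hi_Mb & a$end_Mb > lo_Mb]
}

#' Per-group allele effects at a marker
#'
#' Mean strain phenotype by allele within each strain group; used to detect
#' allele-effect sign flips between sub-populations.
#'
#' @param y Named numeric vector of strain means.
#' @param genotypes A \code{geno_matrix}.
#' @param marker Typed marker id.
#' @param grouping Named character vector of group labels per strain;
#'   defaults to the genotype object's sub-populations.
#' @return Data frame: \code{group}, \code{allele}, \code{mean}, \code{n};
#'   empty group-allele cells have \code{NA} mean and n = 0.
#' @export
marker_effect_by_group <- function(y, genotypes, marker,
                                   grouping = genotypes$subpop) {
  stopifnot(marker %in% colnames(genotypes$calls))
  common <- intersect(names(y)[!is.na(y)], genotypes$strains)
  alle <- genotypes$calls[common, marker]
  grp <- grouping[common]
  out <- expand.grid(group = unique(grp), allele = c("B", "D"),
                     stringsAsFactors = FALSE)
  out$mean <- NA_real_
  out$n <- 0L
  for (k in seq_len(nrow(out))) {
    sel <- grp == out$group[k] & alle == out$allele[k]
    out$n[k] <- sum(sel)
    if (any(sel)) out$mean[k] <- mean(y[common][sel])
  }
  out[order(out$group, out$allele), ]
}
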