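---
title: "Methods: phenome-wide genetic analysis of recombinant inbred panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenome-wide genetic analysis of recombinant inbred panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`riphenome` analyzes multi-battery phenotype surveys of recombinant inbred
(RI) mouse panels such as the BXD set: panels of inbred lines, each a fixed
mosaic of two parental genomes (coded B and D), measured for hundreds of
behavioral and physiological traits with a handful of mice per sex per
strain. This vignette explains the statistical machinery, the choices made
where the design was open, and what the synthetic panel generator does and
does not emulate.

## Per-trait decomposition: strain, sex and their interaction

Each trait is modeled by the two-way general linear model

$$y_{ijk} = \mu + \text{strain}_i + \text{sex}_j +
  (\text{strain}\times\text{sex})_{ij} + e_{ijk}.$$

`fit_strain_sex_glm()` tests each term marginally — each effect adjusted for
all others (non-sequential, Type-III-style sums of squares with sum-to-zero
contrasts) — because the panel is unbalanced: strains contribute 3–11 mice
per sex. The reduced model for a term is formed by deleting that term's
columns from the full model matrix; deleting terms from the formula instead
would silently promote the interaction and test nothing. A trait observed in
a single sex still gets its strain test; sex and interaction tests are
returned as `NA`. Constant traits are flagged degenerate with p = 1 by
convention.

Variance components come in two estimators (`estimate_variance_components()`):

* **REML** (default), the convention for unbalanced designs, fitted with
  `lme4`. In per-sex scopes only the strain component is random; in the
  pooled scope strain, sex and strain-by-sex are all treated as random, the
  convention of variance-component software on such designs.
* **ANOVA / expected mean squares**, the method-of-moments solution, exact
  for balanced layouts and using Searle's effective per-strain sample size
  $n_0 = (N - \sum_i n_i^2/N)/(s-1)$ for unbalanced one-way layouts. Negative
  estimates are truncated at zero and flagged. Normality departures bias both
  estimators; the package records the truncation flag rather than attempting
  a correction.

**Heritability** is the strain intra-class correlation
$h^2 = \sigma^2_{strain} / (\sigma^2_{strain} + \sigma^2_{error})$,
a broad-sense proxy in inbred panels (strain differences are wholly genetic).
Sex and interaction variance are deliberately excluded from the denominator:
$h^2$ then measures the within-sex resemblance of strain replicates, and is
comparable between the per-sex and pooled scopes. Its standard error uses the
classical large-sample intra-class-correlation variance

$$\mathrm{Var}(t) = \frac{2(1-t)^2\,[1+(n_0-1)t]^2}{n_0(n_0-1)(s-1)},$$

with $n_0$ as above — an interpretation of the usual "unbalanced-data
adjustment"; the estimator is isolated in `heritability()` and switchable.

**Partial $\omega^2$** divides each component by the total
($\sigma^2_{strain}+\sigma^2_{sex}+\sigma^2_{int}+\sigma^2_{error}$). Strain
effect sizes are classed *large* above 0.30, *intermediate* in (0.10, 0.30],
*small* at or below 0.10; the boundary values themselves fall in the lower
class (the published inequalities overlap at the boundaries, so ties are
resolved downward).

**False discovery rate** control uses Storey q-values: $\hat\pi_0$ from the
$\lambda$-grid estimator with a cubic smoothing spline extrapolated to the
largest $\lambda$ (grid 0.05–0.95 by 0.05), and
$q_i = \min_{p_j \ge p_i} \hat\pi_0\, m\, p_j / \mathrm{rank}(p_j)$. Forcing
$\hat\pi_0 = 1$ reproduces Benjamini–Hochberg exactly, which is the frozen
oracle in the tests. Fewer than 20 p-values fall back to $\hat\pi_0 = 1$
(the smoother is meaningless there). At threshold $q$, a list of $n$
discoveries carries about $q\,n$ expected false positives
(`expected_false_discoveries()`).

**Sex policy.** A trait is mapped separately by sex when the sex or
interaction q-value falls below 0.05 ("trend toward" a sex difference is
operationalized at the same q threshold as significance; a raw-p variant
is a trivial wrapper away since the decision function takes the two values
directly). Pooled strain means are least-squares means from the
strain + sex + interaction model, which reduce to the equal-weight average of
the two sex-specific strain means whatever the sex counts; per-sex means are
arithmetic. Univariate quality-control flags mark values strictly more than
5 SD from the trait mean; flagged values are reported and retained.

## Sub-population contrast

Old and new RI strain sets can differ systematically. Because mice are
replicates within strains — not independent units — the global comparison
uses the nested model with the alternate F ratio
$F = MS_{subpop} / MS_{strain(subpop)}$ on $(g-1,\ s-g)$ degrees of freedom:
the strain, not the mouse, is the error stratum. Mouse-level error terms
inflate the type-I rate badly under strain heterogeneity; the test suite
demonstrates the contrast (nested ≈ 5%, naive several-fold higher). Sums of
squares are computed on strain means weighted by strain sample size
(Henderson-I analogue); `weighted = FALSE` switches to unweighted strain
means, since the published description does not fix the weighting.

## Haley–Knott genome scans

Scans run on strain means. At any locus, LOD
$= (n/2)\log_{10}(RSS_0/RSS_1)$ from the regression of strain means on the
expected D-allele dosage; for a single regressor this equals
$-(n/2)\log_{10}(1-r^2)$, which is how the scan is vectorized. Between typed
markers (default grid step 1 cM) the dosage is the conditional probability of
D given the flanking genotypes under a marker-to-marker Markov model, with
single-generation Haldane recombination fractions expanded to the RI scale
$R = 4r/(1+6r)$ (sib-mating map expansion). Monomorphic loci score 0; the
scan is invariant to affine transformation of the phenotype.

Genome-wide thresholds come from permuting strain labels against the
genotype rows (preserving marker correlation), rescanning, and recording the
maximum LOD: the *significant* threshold is the 95th percentile (genome-wide
P = 0.05) and the *suggestive* threshold the 37th percentile, i.e.
genome-wide P $= 1 - e^{-1} \approx 0.63$, the criterion of one expected
false positive per scan. Support intervals are one-LOD drop-offs with linear
interpolation between grid points, truncated at chromosome ends; flat-topped
peaks extend to the outermost grid point of the top before the drop is
applied, and exact LOD ties report the leftmost position with co-peaks
listed. Positional candidates are all genes whose half-open [start, end) Mb
span overlaps the support interval at all. Pseudomarker Mb positions are
interpolated linearly between flanking typed markers; cM is the mapping
coordinate, Mb only localizes candidates.

## Genetic correlation

Strain-mean correlations (trait–trait, factor–trait, trait–transcript) are
Pearson by default — the GeneNetwork convention — with a Spearman switch, and
a two-sided p from the t transform on $n-2$ df after an inner join on strain
ids. Expression correlate lists keep probes with raw p below 0.001 (no
multiplicity correction at this stage; candidate lists are filtered
downstream by convergence across analyses) and collapse probes to genes by
maximum |r|; collapsing after thresholding matches the list semantics and
only affects which probe represents a gene.

## Multi-trait factor pipeline

The strain-by-trait mean matrix has more traits than strains, so the sample
correlation matrix is singular. The pipeline:

1. removes strains with strictly more than 25% missing traits,
2. imputes remaining gaps with column (trait) means — valid for data missing
   at random and mean-preserving by construction,
3. standardizes and shrinks the correlation matrix toward the identity with
   the analytic James–Stein-type intensity
   $\lambda^* = \sum_{i\ne j}\widehat{\mathrm{Var}}(r_{ij}) / \sum_{i\ne j}
   r_{ij}^2$ (clipped to [0,1]); the result is positive definite whenever
   $\lambda^* > 0$, hence invertible even for $n < p$,
4. selects the factor count by parallel analysis (eigenvalues above the 95th
   percentile of random-data eigenvalues; 100 random datasets) and optimal
   coordinates (eigenvalue above its linear extrapolation from later
   eigenvalues *and* above the parallel reference, stopping at the first
   failure). Both are reported; `k` can also be fixed by the caller, since
   fitted, selected and interpreted factor counts are legitimately different
   quantities in this kind of analysis,
5. fits the unrotated maximum-likelihood factor model
   $\Sigma = \Lambda\Lambda' + \Psi$ by EM, initialized by principal axes
   with squared-multiple-correlation communalities, converged when the
   log-likelihood gain drops below 1e-10 (or 10,000 iterations), with
   uniquenesses floored at 1e-3 (Heywood cases flagged). Because the
   likelihood is invariant to orthogonal rotation of the factor space, the
   fit is reported in the canonical ML orientation ($\Lambda'\Psi^{-1}\Lambda$
   diagonal) — this identifies the solution deterministically without
   applying any interpretive rotation. Factors are ordered by variance
   explained (column sums of squared loadings over $p$) and sign-fixed so
   each column's largest loading is positive,
6. computes Thomson regression scores $F = Z R^{-1}\hat\Lambda$ using the
   shrunk $R$ (the raw one may be singular), and
7. flags factors explaining less than 1.3% of variance as excluded from
   interpretation.

Factor scores feed straight back into the genome scan, which is how
multi-trait QTL mapping is realized. Note that equal-strength latent factors
are not identifiable even in the canonical orientation (their subspace can be
rotated freely); recovery diagnostics in the tests therefore plant factors of
distinct strength.

## Multivariate extreme strains

For a chosen trait set, $D^2 = (x-\bar x)' S^{-1} (x-\bar x)$ per strain,
with mean and covariance estimated over complete strains *including* the
candidate (the simpler reading; a leave-one-out variant is behind a flag,
and a singular $S$ falls back to the shrunk estimate). Under multivariate
normality $D^2 \sim \chi^2_{df=\#traits}$; strains with upper-tail p below
0.05 are flagged. Per-trait standing labels (high / intermediate / low) are
panel tertiles — an interpretation, since the labels have no published
definition. $D^2$ is affine-invariant, so raw versus standardized traits
matter only through missing-data handling.

## Bipartite integration and enrichment

Every candidate list (positional candidates of one QTL, expression
correlates of one trait in one tissue) is a phenotype vertex; genes are the
other class; edges record membership (deduplicated). Gene degree measures
cross-phenome connectivity; ties in the ranking break by gene id so slices
are deterministic, and the top 5%/10% slices take exactly
$\lceil f\,n\rceil$ genes. A `min_degree = 2` filter can drop
singleton genes (convergence filtering); it is off by default. Pathway
over-representation of a slice is the one-sided hypergeometric tail
$P(X \ge k)$ with the full annotation as universe (configurable), with an
optional Benjamini–Hochberg column; degree rankings are biased toward traits
measured in many assays, which an optional collapse of phenotype vertices by
trait family would mitigate (not applied by default, matching the published
workflow).

## The synthetic panel generator

The generator emulates the study design directly at the RI-statistics level
rather than by forward-in-time breeding: each chromosome of each strain is a
two-state Markov chain over the marker grid with stationary allele
frequencies 1/2 and transition probability $R = 4r/(1+6r)$ of the Haldane
$r$ for the inter-marker distance. Defaults encode the emulated study
population: two sub-populations of 32 (older) and 63 (recent) strains, 3–11
mice per sex per strain, 250 traits across six batteries with strain
variance fractions drawn from 0.05–0.7, modest sex and interaction
fractions, ~5% missing entries, 10 loci fixed for B in the older
sub-population, and — because the real panel's marker density is not
published — 20 chromosomes of 100 cM with 50 markers each and a 2 Mb/cM
physical scale. Phenotypes follow
$y = \mu + \sum_m a_m g_m + u_{strain} + s_{sex} + (us) + e$ with $g$ coded
−1/+1 and random components scaled to hit the configured variance fractions;
expression matrices carry plantable cis effects at each gene's nearest
marker so expression–trait genetic correlation is constructible by design.

What it does *not* emulate — and therefore what passing tests do not
establish about real data: non-normal and heteroskedastic trait
distributions (common in behavior), litter/site/batch covariates, residual
heterozygosity or genotyping error (H/U calls are supported by the readers
but not emitted), linkage disequilibrium beyond the Markov approximation,
epistasis, and correlated measurement error across traits within a battery.
Tests on this generator validate the estimators' correctness and
calibration, not robustness to those features.

## Problem sizes and determinism

Simulation-backed checks use deliberately chosen sizes: heritability
recovery uses 60 strains × 8 mice/sex over 200 replicates per truth level;
type-I calibration uses 400 replicates; permutation calibration uses 200
null traits at 500 permutations each on a 40-strain, 10-chromosome panel
(the production default remains 1000 permutations); factor recovery uses
200 strains × 30 traits. Every stochastic function takes an explicit seed,
pipeline outputs carry a provenance header with seed and configuration
hash, and reruns with the same seed are byte-identical.

## Known limitations

Single-QTL scans only (no composite-interval or multiple-QTL models, no
epistasis scan); no robust (MCD) covariance for the outlier stage; no
pedigree simulation; no factor rotation or automatic factor labeling; the
pooled-scope ANOVA variance components use the balanced expected-mean-squares
algebra (REML is the default precisely because the panels are unbalanced);
and q-value estimation needs a reasonably large p-value collection for a
stable $\hat\pi_0$.
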