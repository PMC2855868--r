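Package: riphenome
Title: Phenome-Wide Genetic Analysis of Recombinant Inbred Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis toolkit for multi-battery phenotype surveys of
    recombinant inbred (RI) mouse panels such as the BXD set. Provides
    per-trait strain/sex general linear models with partial omega-squared
    effect sizes, intra-class-correlation heritability with unbalanced-design
    standard errors, Storey q-value false discovery rate control, nested
    sub-population F-tests, Haley-Knott regression genome scans on strain
    means with permutation-derived suggestive and significant thresholds and
    one-LOD support intervals, strain-mean genetic correlation against
    expression matrices, shrinkage-covariance maximum likelihood factor
    analysis for multi-trait QTL mapping, Mahalanobis-distance detection of
    multivariate extreme strains, and bipartite gene-phenotype integration
    with hypergeometric pathway enrichment. A synthetic RI panel generator
    with known genetic architecture supports testing every stage without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
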