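Package: metameta
Title: Multi-Cohort Metagenomic Meta-Analysis of Differential Abundance,
    Co-Occurrence Networks, and Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-analysis of species-level metagenomic count data
    across multiple case-control cohorts. Implements direction-divergence
    filtering of discordant species, a pairwise fold-change rank-sum
    meta-analysis with permutation-based estimated percentage of false
    positives (pfp), confounder detection and log-linear adjustment,
    stratified (van Elteren) Mann-Whitney tests, Dirichlet-multinomial
    power simulation, SparCC compositional correlation with Fisher r-to-Z
    meta-combination and weighted co-occurrence network metrics, radial-kernel
    SVM evaluation with cross-validation and leave-one-cohort-out schemes,
    and species-to-function association with MaxP combination and FDR
    control. Includes a synthetic multi-cohort data generator emulating the
    statistical structure these analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    vegan,
    igraph,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    biomformat,
    yaml,
    optparse
Config/testthat/edition: 3
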