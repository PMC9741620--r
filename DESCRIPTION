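Package: inbredkin
Title: Kinship, Inbreeding and Individual Identification in
    Low-Diversity Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the genetic analysis of small, isolated and highly
    inbred populations genotyped on reduced-representation SNP panels.
    Implements the standard panel filters (call rate, minor allele
    frequency, one SNP per locus, linkage-disequilibrium pruning),
    per-individual heterozygosity rates and inbreeding coefficients
    (moment and maximum-likelihood estimators), two contrasting pairwise
    relatedness estimators (an allele-frequency-free robust counting
    estimator and a nine-condensed-identity-state maximum-likelihood
    estimator with locus-bootstrap confidence intervals), exact pedigree
    kinship and inbreeding with a gene-dropping Monte Carlo oracle, a
    genotype-crossing pedigree simulator, a calibrated synthetic-panel
    generator emulating structured low-diversity populations, and
    reproducible individual-identification and estimator-recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
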