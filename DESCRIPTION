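Package: miwas
Title: Modality-Level Imaging-Wide Association Tests from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Gene-based instrumental-variable tests of whether an entire
    brain-imaging modality (structural, diffusion or functional MRI) carries a
    genetically regulated causal pathway to a disease trait, using only GWAS
    summary statistics and a linkage-disequilibrium reference panel. Implements
    a SKAT-style variance-component score statistic over the genetically imputed
    imaging-derived phenotypes of one modality, adjusting for horizontal
    pleiotropy through other modalities and for residual direct genetic effects
    via an Egger-type burden column, with mixture chi-square p-values (Davies-type
    numerical inversion, Liu moment matching, and Monte Carlo). Includes the
    summary-statistics Stage-1 weight construction (LD clumping, z-score to
    marginal-beta transform, joint weights through the inverse LD matrix, F-test
    screening), univariate comparator tests, and a simulation framework for
    Type-I error and power evaluation with correlated binary genotypes,
    confounded multi-modality imaging phenotypes, and continuous or binary traits.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
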