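Package: cistriad
Title: Integrative Cis-Mapping of Methylation, Expression and Allelic Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for joint cis-QTL analysis of DNA methylation,
    total gene expression and allelic expression in a population cohort.
    Provides permutation-calibrated empirical-FDR mapping of mQTLs, eQTLs,
    aeQTLs and methylation-expression correlations within 250 kb cis windows;
    left-to-right hidden Markov model smoothing and segmentation of allelic
    expression log-ratios into aeRegions; quantile normalization and variance
    filtering of array data; genomic-context annotation of CpG probes (TSS,
    island/shore/shelf, chromatin marks, modality of the beta distribution);
    and integration stages (emQTL intersection, MAF-matched enrichment,
    cross-validated variance partitioning of expression into sequence and
    methylation components, Fisher term enrichment). A synthetic multi-omic
    cohort generator with planted effects supplies ground truth so the whole
    pipeline is exercisable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    limma,
    MASS,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
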