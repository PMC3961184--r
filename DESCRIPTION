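Package: resistscope
Title: Multi-Assay Inference of Metabolic and Target-Site Insecticide
    Resistance Mechanisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for attributing insecticide-resistance
    phenotypes in mosquito populations to their genetic mechanisms.
    Implements two-colour microarray contrast estimation with empirical-Bayes
    moderation and FDR control, a resistance-ranked consensus filter that
    combines evidence across experimental designs and aggregates probes to
    genes, efficiency-corrected delta-delta-Ct relative expression and qPCR
    copy-number quantitation, TaqMan endpoint allelic-discrimination genotype
    calling with heterozygote dye-balance analysis, and bioassay statistics
    (synergism odds ratios, log-dose LC50 estimation with Fieller intervals,
    exact Mann-Whitney discriminating-dose tests, and in-vitro substrate
    depletion). A synthetic-data generator plants ground truth for every
    stage so the whole chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
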