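Package: nitroscape
Title: Biogeography of Nitrogen-Cycle Genes from Annotated Soil Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling nitrogen-cycling functional genes across soil
    metagenome collections annotated with KEGG Orthology (KO) terms. Computes
    per-sample gene abundance, richness and variance from Estimated Copy
    tables, calls operon completeness for nitrogen-cycle proteins, screens
    Pearson correlations between genes and biogeochemical variables with
    significance masking, discretizes covariates and mines association rules
    (support, confidence, lift) with a level-wise Apriori miner, and
    interpolates environmental fields over irregular sampling layouts by
    Delaunay triangulation with piecewise-linear (barycentric) evaluation.
    Includes a synthetic survey generator with planted correlations and rules
    so every stage of the pipeline can be exercised end to end.
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
    interp,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
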