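Package: rnaivar
Title: Natural Variation in RNA Interference Pathways: Expression
    Variance, Allele Fates, Penetrance and Transcript Knockdown
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analyses for studies of natural variation in
    RNA interference (RNAi) competence across wild Caenorhabditis
    elegans strains. Provides expression-matched resampling enrichment
    of strain-wise expression variance for a focal gene set, rule-based
    classification of allele fates (pseudogenization and functional
    divergence) from population variant data, per-gene nucleotide and
    haplotype diversity, quasibinomial penetrance models with
    Tukey-style contrasts and complementation-pattern calling, linear
    models of penetrance over reproductive lifespan, excess-mass
    multimodality testing of per-embryo transcript counts, and
    stage-adjusted ANCOVA with omega-squared effect sizes. A seeded
    synthetic-data generator emulates the statistical structure of each
    input so pipelines can be exercised and calibrated end to end.
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
    multcomp,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
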