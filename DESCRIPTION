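Package: phenomore
Title: Metabolic Knockout Phenotype Discovery and Promoter Cassette Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discovery pipeline for multi-center knockout-mouse metabolic
    phenotyping data. Computes mutant/wild-type ratios per center and sex with
    body-mass residual adjustment for oxygen consumption and metabolic rate,
    calls percentile outliers into strong-phenotype gene lists, tests candidate
    gene sets by permutation, scores cross-phenotype GWAS association with the
    CPMA likelihood-ratio statistic, mines shared promoter TFBS cassettes
    (ordered multi-element regulatory modules with distance constraints),
    builds phenotype-linked regulatory gene networks, and validates
    cassette-based phenotype prediction with Fisher's exact test. A synthetic
    data module generates every input with the statistical structure the
    analysis assumes, so the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    data.table,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
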