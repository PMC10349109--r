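Package: myxotriage
Title: Rare-Variant Triage and Expression Gating for Left Atrial Myxoma Exomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the variant-triage analysis used to
    nominate candidate genes in sporadic left atrial myxoma from multi-sample
    whole-exome variant tables: region/function/minor-allele-frequency
    preliminary screening, hereditary-versus-somatic hypothesis set logic over
    tumor, blood and normal-tissue samples, recurrent-artifact and lab-control
    subtraction, consensus in-silico pathogenicity voting over six predictors,
    ACMG/AMP evidence-code classification, and RPKM-based expression gating.
    Includes a seed-deterministic synthetic cohort generator with planted
    ground truth standing in for the study's raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
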