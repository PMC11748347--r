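Package: raredx
Title: Virtual-Panel Variant Prioritization and Gene-Dose CNV Calling for
    Rare-Disease Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tertiary-analysis toolkit for targeted rare-disease gene
    panels. Applies diagnostic-grade virtual panels, inheritance-aware
    frequency/classification/zygosity filters and compound-heterozygote
    detection to annotated small-variant calls; calls copy-number variants
    from batch read-depth matrices using per-target gene dose and z-scores,
    with comparative-Ct (2^-ddCt) confirmation arithmetic; computes panel
    coverage QC (fold-80 base penalty, coverage thresholds, commonly
    uncovered exons); classifies case outcomes and summarizes cohort
    diagnostic yield. Ships a seeded synthetic-data generator so the whole
    pipeline is exercisable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
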