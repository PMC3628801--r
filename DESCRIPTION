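Package: recessmap
Title: Homozygosity Mapping and Variant Prioritization for Recessive Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps fully penetrant recessive Mendelian traits in small
    case/control cohorts, the workflow used for inherited disorders in
    inbred dog breeds. Provides PLINK-text (PED/MAP) and VCF ingestion,
    marker quality control with an exact Hardy-Weinberg test, per-marker
    allelic chi-square association with genomic inflation and max-T
    permutation correction, shared-homozygosity run detection with critical
    interval delineation, a hard-filter variant prioritization cascade
    (interval intersection, panel subtraction, coding-effect restriction),
    HGVS coding-consequence annotation for SNVs and frameshifts, cohort
    segregation statistics (recessive concordance, carrier frequency,
    genotype r-squared), and a synthetic-cohort simulator with planted
    ground truth for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    vcfR,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
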