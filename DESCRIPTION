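Package: popcis
Title: Ancestry-Differentiated cis-eQTL Mapping with Survival Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A multistep cis-eQTL discovery pipeline for ancestry-enriched
    susceptibility loci: variant quality control (imputation accuracy, minor
    allele frequency, Hardy-Weinberg equilibrium), cross-population
    allele-frequency differentiation by chi-square with target-ancestry
    enrichment, cis-window linear regression of expression on genotype
    dosage with Benjamini-Hochberg false discovery rate control, and a
    downstream clinical validation arm (quantile normalization, Wilcoxon
    rank-sum differential expression, median-dichotomized Kaplan-Meier /
    log-rank survival comparison, and Cox proportional hazards regression).
    Includes a Balding-Nichols simulator producing population-structured
    genotypes, cis-regulated expression, and censored survival times with
    known ground truth, so every pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    survival,
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
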