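Package: toxassoc
Title: Exome-Array Association Analysis of Fluoropyrimidine Toxicity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Case-control association pipeline for adverse drug reactions to
    fluoropyrimidine (5-fluorouracil / Capecitabine) chemotherapy, built
    around exome-array genotype data. Provides PLINK binary fileset input
    and output, a synthetic-cohort generator with liability-threshold
    toxicity grades, phenotype dichotomization (DMN, DM, HFS, severe HFS),
    genotype quality control including an exact Hardy-Weinberg test and
    method-of-moments relatedness estimates, ancestry principal components
    with iterative outlier removal, single-variant logistic association
    with genomic-control diagnostics, gene-level rare-variant tests (CMC
    collapsing and SKAT with Beta(1,25) weights), a region-wide enrichment
    test based on phenotype permutation of summed chi-squared statistics,
    and Bonferroni/power design calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
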