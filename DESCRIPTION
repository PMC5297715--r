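Package: spex
Title: Somatic Variant Filtering, Indel Impact and Exome Homozygosity
    Mapping for Paired Tumor-Normal Exomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for small paired tumor-normal whole-exome
    cohorts, built around a nine-patient study of solid pseudopapillary
    tumor of the pancreas. Implements the somatic filtering cascade
    (matched-normal subtraction, consequence and population-frequency
    filters), classification of coding indels into frameshift, in-frame
    and splice-site categories with High/Moderate/Low impact tiers,
    sliding-window exome homozygosity (run-of-homozygosity) mapping with
    marker-level genotype calls, cohort-level recurrence and chromosome
    summaries with two-sided Fisher exact group comparisons, score-
    thresholded interaction-network hub ranking, and a seeded synthetic
    cohort and marker-map generator with truth labels for end-to-end
    validation. Ships the study's variant tables as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
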