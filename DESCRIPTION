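Package: ashmscreen
Title: Genome-Wide Screening for Allele-Specific Histone Modification,
    Methylation and Expression at Heterozygous SNPs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A statistically rigorous screen for allele-specific chromatin
    state at heterozygous SNPs from multi-assay allele-resolved read counts.
    Calls allele-specific histone modification (ASHM) with a cross-dataset
    contingency-table test that is immune to nucleosome-occupancy shifts and
    false-positive heterozygotes, strand-specific allele-specific DNA
    methylation (ASM) with Fisher exact tests and adjacent-polymorphism
    annotation, and allele-specific expression and PolII binding (ASE/ASP)
    with binomial tests. Includes heterozygote validation from bisulfite
    allele support, Hardy-Weinberg and coverage quality control, clustering
    of imbalance profiles with driver-modification identification, proximity
    enrichment against annotation tracks, posterior-odds and Bonferroni
    calibration, and a seeded synthetic-data generator with known truth for
    end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
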