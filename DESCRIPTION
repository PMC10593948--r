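Package: consensusTR
Title: Consensus Genotyping and Population Analysis of Tandem Repeats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Merges discordant tandem-repeat (TR) genotypes produced by
    multiple short-read genotypers (sequence-resolved and copy-number
    callers) into a single scored consensus callset, using quality-weighted
    voting over unified allele representations. Includes the supporting
    quality-control and population-genetics toolkit: a motif-complexity
    filter for VNTR repeat units, Mendelian-inheritance analysis over
    trios, locus-level filters (call rate, Hardy-Weinberg equilibrium,
    Mendelian error rate), allele-frequency spectra, heterozygosity,
    population-specific repeat-expansion detection, leave-one-out
    imputation concordance, SNP-TR linkage disequilibrium and tag-SNP
    search, and a fully seeded synthetic-cohort generator that produces
    every input format the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
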