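Package: msatkit
Title: Microsatellite Marker Discovery, Screening and Characterization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for developing microsatellite (SSR) markers from shotgun
    sequencing reads and characterizing them in diploid populations. Finds
    maximal perfect 2-6 bp tandem repeats in FASTQ reads, screens candidate
    loci by exact primer-occurrence counts against genome-coverage bounds,
    bins raw fragment-size peak calls into integer allele labels with an
    explicit ambiguity criterion, and computes per-locus summaries: observed
    and expected heterozygosity, Monte-Carlo Hardy-Weinberg tests with
    multiple-testing adjustment, Brookfield null-allele frequencies,
    rarefaction allelic richness and replicate genotyping error rates.
    Includes ground-truthed simulators for reads, genotype matrices and
    peak-call tables so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    S4Vectors,
    graphics,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
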