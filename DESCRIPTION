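Package: mgbssr
Title: Multiple-Genome-Based Discovery of Polymorphic SSR Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for discovering polymorphic simple-sequence-repeat (SSR,
    microsatellite) markers by comparative screening of two or more related
    genome assemblies. Detects perfect SSRs with 3-6 nt motifs, extracts
    repeat cores with flanking sequence, and runs a five-stage cross-genome
    screen (self-uniqueness, orthologous flank matching at >= 90% identity,
    repeat-count comparison, flank-mutation filtering, and an all-genomes
    polymorphism requirement) to retain loci whose repeat counts differ among
    every screened genome. Downstream marker tools cover primer-pair criteria
    (amplicon size, melting temperatures, dimers, specificity, M13 tailing)
    and fluorescent multiplex panel assembly, per-marker diversity statistics
    (Na, Ne, Ho, He, PIC) from ploidy-aware genotype tables, digital
    molecular identity cards, and diversity analysis via 0/1 allele matrices,
    neighbor-joining trees, and principal coordinates analysis. Includes a
    seeded synthetic-data generator planting SSR loci of known polymorphism
    classes, used as ground truth throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
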