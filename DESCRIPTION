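Package: mitostruct
Title: Structural Heteroplasmy and Repeat-Mediated Recombination in Plant
    Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing structural dynamics of circular plant
    mitochondrial genomes. Detects direct and inverted repeat pairs under a
    minimum-length and maximum-mismatch contract, simulates repeat-mediated
    intra- and intermolecular recombination including the two-step scenario
    that interconverts two alternative genome arrangements, quantifies
    structural heteroplasmy by classifying junction-spanning sequencing reads
    against the four diagnostic repeat junctions of a genome-structure pair,
    diagnoses gene pseudogenization (frameshift indels, premature stop
    codons, 3'-truncation) against an intact reference CDS, and classifies
    the cis/trans splicing configuration of a group-II intron such as
    nad1i728. A synthetic-data module generates circular genomes with
    planted repeats, derived alternative structures, read mixtures with
    known ground truth, and decayed CDS sets, so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
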