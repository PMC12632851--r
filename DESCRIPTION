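Package: repeatweaver
Title: Tandem-Repeat cDNA Simulation and Motif Discovery for
    Telomerase-Like Reverse Transcriptases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying noncoding-RNA-templated synthesis of
    tandem-repeat single-stranded cDNA by bacterial defense-associated
    reverse transcriptases (DRT10) and related telomerase-like enzymes.
    Detects and ranks A-B-A' direct-repeat template patterns in ncRNA
    sequences, predicts the encoded cDNA repeat motif, and designs
    chimeric templates for arbitrary repeats; simulates the iterative
    extend/dissociate/realign repeat-addition cycle under configurable
    base-pairing rules to produce cDNA products and synthetic
    sequencing read sets; and analyses sequencing reads by partitioning
    them against a reference, discovering differentially enriched
    k-mer motifs between conditions, and quantifying tandem repeats
    through motif position graphs, longest-run histograms,
    flanking-context logos and period estimation, with counts-per-million
    normalization throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
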