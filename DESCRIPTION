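Package: g4scape
Title: Genome-Wide G-Quadruplex Detection and Regulatory-Region Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects putative G-quadruplex (G4) forming sequences on both
    strands of a genome with a G4Hunter-style run-length score and sliding
    window, derives strand-aware regulatory regions (promoters of several
    lengths, transcription start site windows, gene/exon/CDS/intron/UTR)
    from GFF3 annotation, and computes per-region G4 densities,
    coding-versus-template strand bias with fold differences and exact
    binomial tests, gene classification by G4 burden, gene-set counting,
    chromosome-level feature correlations, and windowed density tracks.
    Differential-expression tables can be overlaid to compare G4 patterns
    of up- and downregulated gene sets. A synthetic-genome generator with
    planted motifs and known ground truth makes every stage testable
    end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
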