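Package: antisenseMotifs
Title: Antisense Nrd1/Nab3 Degradation-Signal Encoding in Yeast Coding Sequences
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to study how Saccharomyces cerevisiae protein-coding
    sequences encode Nrd1/Nab3 termination-and-degradation signal motifs on
    the antisense strand through biased synonymous-codon usage. Provides
    strand-aware scanning for the Nrd1 (UGUA, GUAG, UGUAG) and Nab3 (UCUU,
    CUUG, UCUUG) consensus motifs with a longest-match rule, classification
    of ORFs by antisense CUT/SUT overlap, metagene density profiles of
    predicted sites around start and stop codons, expression-normalised
    PAR-CLIP occupancy profiles, a codon-usage expectation model for
    observed-versus-expected site counts over amino-acid pair and triplet
    universes, codon adaptation index computation, and a fully seeded
    synthetic-data generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings,
    nortest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools,
    seqinr,
    nortest
Config/testthat/edition: 3
biocViews: Genetics, Transcription, MotifAnnotation, Coverage, Sequencing
RoxygenNote: 7.3.3
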