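Package: prionevo
Title: Conservation of Prion-Like Composition and Sequence Across Fungal Clades
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying how well prion-forming and
    prion-like domains of budding yeast conserve their sequence and their
    N/Q-biased, prion-like amino-acid composition across nested taxonomic
    levels. Detects orthologs by bidirectional best hits over exact
    Smith-Waterman alignments, builds per-family multiple alignments with a
    progressive profile aligner, scores per-column conservation by a
    normalized entropy measure, scores prion-like composition with a
    two-state hidden Markov model, and combines per-ortholog prion scores
    into an evolutionarily weighted prion score (EWPS) under percent-identity
    or bitscore-ratio weighting. Includes a sequence-evolution simulator that
    plants N/Q-rich domains in ortholog families across nested clades so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
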