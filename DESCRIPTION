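Package: rg4evo
Title: Evolutionary Analysis of RNA G-Quadruplex Motifs in Eukaryotic Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the post-detection evolutionary analysis of RNA
    G-quadruplexes (rG4s). Provides a putative quadruplex sequence (PQS)
    scanner covering canonical, long-loop, bulged and two-quartet motif
    grammars with an integer canonicality score (the number of tri-guanine
    G-tracts, capped at 4); transcript coordinate mapping and gene-region
    assignment (5'UTR/CDS/3'UTR); codon-level characterization of
    coding-sequence rG4s (codon enrichment against parent-gene baselines,
    G-tract codon-span decomposition, amino-acid usage in tracts); overlap
    of rG4s with repetitive elements, peptide low-complexity regions,
    microRNA seed sites and splice junctions; gene-family age assignment by
    last-common-ancestor lookup on dated species trees and Ohnolog
    stratification; conservation statistics from whole-genome multiple
    alignments (per-species PQS presence and sequence identity, nested
    vertebrate clade summaries, positional conservation); parsimony
    reconstruction of ancestral windows with canonicality-drift
    classification; and a fully seeded synthetic-data generator that
    emulates every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
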