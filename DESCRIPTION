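Package: colorbwt
Title: Colored Run-Length BWT Index for Taxonomic Classification of Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a run-length-compressed Burrows-Wheeler index represented
    as a move structure whose BWT runs carry "colors", i.e. the sets of source
    documents (genomes or taxa) contributing suffixes to each run. Reads are
    queried with pseudo-matching-length (PML) computations that tally run
    colors into per-document scores, enabling binary (in-index vs
    unclassified), multi-class, and taxonomic (lowest-common-ancestor)
    classification of long sequencing reads against pangenome-scale reference
    collections. Includes repositioning with LCP-based thresholds or
    threshold-free heuristics, dense and sparse color-table encodings with
    occupancy statistics, rank-level evaluation metrics with a six-way read
    categorization, and a synthetic pangenome and read simulator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
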