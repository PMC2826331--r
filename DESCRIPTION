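Package: phyloscaf
Title: Phylogeny-Weighted Comparative Contig Scaffolding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Orders and orients the contigs of a draft bacterial genome by
    comparison against several finished genomes of related species. Contigs are
    matched against each reference with a q-gram filter followed by banded
    verification, candidate contig adjacencies are scored with a
    phylogeny-weighted mixture of two Gaussian kernels (insertions/deletions and
    lost sequencing fragments), and the resulting contig adjacency graph is
    resolved either into an optimal linear order (exact branch-and-bound
    travelling-salesman search) or into a conflict-tolerant layout graph via a
    relaxed multi-fragment greedy heuristic. Includes a rearrangement-aware
    genome simulator for validation, adjacency-level evaluation against a
    reference order (TP/FP/TPR/PPV, N50), Graphviz DOT export, and readers for
    BLAST tabular and nucmer coordinate match tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
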