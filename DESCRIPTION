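Package: orthogain
Title: Two-Proteome Ortholog Gain/Loss and Sequence-Variation Analysis
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale comparative-proteomics pipeline for a pair of
    related species: representative-isoform selection, reciprocal-best-hit
    orthology from 12-column tabular alignments (or a built-in affine-gap
    local aligner), three-way gene classification (shared / A-only /
    B-only), protein-family expansion and contraction counting,
    hypergeometric pathway enrichment of lineage-missing genes at gene and
    node level, source-to-phenotype path-affectedness on pathway graphs,
    and a screen for large (>25 aa) insertions and deletions in ortholog
    alignments with domain-overlap reporting and six-frame genome
    verification. Includes a synthetic-data generator that emits paired
    proteomes with planted orthologs, family dynamics, pathway lesions and
    indels alongside a ground-truth ledger, so the whole pipeline is
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
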