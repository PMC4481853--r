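Package: orthoblockr
Title: Event-Based Analysis of Gene Block and Operon Evolution in Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the evolution of bacterial gene blocks (operons)
    with an event-based method. Orthologous gene blocks ("orthoblocks")
    are assembled in target genomes relative to a curated reference
    operon set using genomic context (neighboring genes at most 500 bp
    apart on the same strand) and strict sequence homology (BLAST
    e-value at most 1e-10). Pairwise split, deletion and duplication
    event distances are computed between every pair of taxa, summarised
    as conservation rankings, and visualised as phylogeny-ordered
    z-score matrices ("phylomatrices"). A forward simulator of gene
    block evolution along a tree provides self-contained synthetic data
    with ground-truth event logs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
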