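Package: epidrift
Title: Epigenetic Drift Analysis of Histone Modification States in Organoid Culture
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for tracking epigenetic drift of H3K4me3/H3K27me3 histone
    modification states between tissue and organoid samples. Builds consensus
    peak lists from replicate ChIP-seq peak calls (both-replicates or
    fold-enrichment rescue), encodes per-gene binary modification codes from
    promoter and gene-body overlap, clusters gene profiles with a
    self-organizing map (portraits, correlation clusters, under-expression
    spots, K-means landscapes, correlation spanning trees), calls state
    transitions between sample groups, and integrates RNA-seq via RPM/RPKM
    normalization, log expression differences, gene-set Z-scores and
    hypergeometric over-representation tests. Includes a synthetic-data
    generator with planted ground truth so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
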