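Package: pcgtopo
Title: Calling and Topology Profiling of Broad H3K27me3 Polycomb Chromatin Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls broad H3K27me3-enriched (Polycomb-group) chromatin domains
    from replicate binned ChIP-seq coverage using a Poisson-calibrated coverage
    minimum, a composite replicate threshold, a bin-density rule and a
    replicate-correlation filter; quantifies nucleosome-scale conservation of
    domain topology via local correlation estimates (LCE), local coverage sums
    (LCS) and an eigenvalue-based correlation summary; matches domains across
    differentiation and postnatal-age conditions with consistency-filtered
    span-change calls; and links domain properties to gene-expression change
    with resampling null models, span-matched virtual-region controls and
    Benjamini-Hochberg FDR. A synthetic-data generator with planted domains
    and remodeling modes supports end-to-end validation against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
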