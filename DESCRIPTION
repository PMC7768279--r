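Package: prescout
Title: Discovery and Validation of Cell-Type-Specific Putative Regulatory Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for discovering putative regulatory elements (pREs) that are
    preferentially active in a cell population of interest (such as cortical
    interneurons) from differential histone-modification ChIP-seq enrichment.
    Provides genomic interval arithmetic and BED input/output, a simplified
    Poisson broad-peak caller with a likelihood-ratio differential classifier,
    replicate-consistency assessment via the two-component Gaussian copula
    mixture model (irreproducible discovery rate), construction of
    high-confidence differential peak sets with multi-evidence annotation and
    ranking of candidate elements, motif and GREAT-style region-gene term
    enrichment, current-clamp electrophysiology feature extraction with
    rule-based fast-spiking classification, delta-delta-Ct ChIP-qPCR fold
    change, the supporting inferential statistics, and synthetic-data
    generators with known ground truth so that the whole pipeline can be
    exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
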