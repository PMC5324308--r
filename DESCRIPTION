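Package: islandrep
Title: Broad-Island ChIP-Seq Enrichment, Repeat-Element Statistics and
    Retroelement Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for heterochromatin ChIP-Seq and
    differentiation RNA-Seq studies. Calls broad read-enriched islands
    (SICER-style window/gap clustering against an Input track), compares
    island densities between conditions, quantifies enrichment of
    repeat-element classes, families and subfamilies in island sets
    against matched random-region nulls with Kolmogorov-Smirnov ECDF
    statistics, quantifies retroelement de-repression from RNA-Seq read
    tracks, computes an ordering statistic for accelerated
    differentiation in knockdown time courses with bootstrap errors and
    a per-sample shuffle null, and relates retroelements to nearby gene
    expression. Ships a deterministic synthetic-data generator with
    known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
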