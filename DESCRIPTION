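Package: cohesinscape
Title: Differential Cohesin ChIP-Seq Analysis with EM Peak Calling and
    Expression Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for studying how a genome-wide reduction
    in cohesin loading (as in Nipbl haploinsufficiency, the primary cause of
    Cornelia de Lange syndrome) reshapes cohesin ChIP-seq binding and target
    gene expression. Provides an expectation-maximization peak caller that
    re-weights multi-mapping reads, Poisson enrichment scoring with a
    preimmune-control empirical false discovery rate, depth-matched
    subsampled peak counting, 100-bp bin log-ratio quantification of global
    binding reduction, precedence-based genomic feature annotation with
    resampling baselines, position-weight-matrix motif scanning calibrated
    against random genomic regions, a Kolmogorov-Smirnov running-enrichment
    statistic linking binding to expression rank, chromosome conformation
    capture (3C) band-intensity normalization, and a synthetic isogenic
    wild-type/mutant experiment generator with planted ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
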