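Package: lncnet
Title: Guilt-by-Association Functional Inference for lncRNAs from
    Case-Control Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable implementation of the long non-coding RNA
    (lncRNA) inference workflow used in two-group expression-profiling studies
    of diffuse large B-cell lymphoma: quantile normalization and differential
    expression calling by signed fold change and false discovery rate,
    lncRNA-mRNA coexpression with Pearson correlation thresholds,
    guilt-by-association functional annotation by hypergeometric term
    enrichment, cis-regulatory neighbor calling within a genomic window,
    TF-lncRNA(-target) regulatory network construction with top-N core
    extraction, and 2^-deltaCt qPCR relative quantification. Ships a synthetic
    data generator with planted, machine-readable ground truth so every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    yaml,
    fgsea,
    Biostrings,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    xml2,
    optparse,
    withr
Config/testthat/edition: 3
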