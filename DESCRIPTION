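Package: nascentr
Title: Nascent Transcription, eRNA Enhancer and ChIP-seq Integration Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: De novo detection of nascent transcription units from stranded
    GRO-seq coverage, promoter-proximal pausing indices, negative-binomial
    differential transcription calling with RPKM/fold-change/FDR gates,
    classification of eRNA-producing enhancers (bidirectional intergenic and
    antisense intragenic), fold-enrichment ChIP-seq peak calling with
    replicate consensus, peak-to-gene association, time-course binding
    categories and pairwise co-occurrence matrices. Ships a fully seeded
    synthetic-data generator with ground truth so every stage of the
    pipeline can be exercised and validated end-to-end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    edgeR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
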