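Package: coreCRC
Title: Core Transcriptional Regulatory Circuitry Inference from Cofactor
    Occupancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers the core transcriptional regulatory circuitry (CRC) of a
    cell from Mediator (MED1), Cohesin (SMC1A) and NIPBL ChIP-Seq peak sets
    together with transcription factor peaks and binding-motif models:
    co-occupancy statistics and principal-component structure of occupied
    regions, CTCF-based partition of Cohesin sites, chromatin-state overlap
    profiles, position-weight-matrix motif enrichment in cofactor-occupied
    regions, cross-referencing of co-occupying factors with enriched motifs,
    circuitry-graph construction with autoregulation detection, and
    hypergeometric pathway enrichment. A synthetic-data generator with planted
    ground truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
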