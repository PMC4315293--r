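Package: cnvtu
Title: Replication-Stress CNV Hotspots and Large Active Transcription Units
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit linking replication-stress-induced copy-number
    variant (CNV) hotspots and common fragile sites to large active
    transcription units. Merges de novo CNV calls into regions and classifies
    singletons, clusters and hotspots; assesses clustering and feature
    enrichment by randomized-placement Monte Carlo simulation over the
    mappable genome; calls transcription units from strand-specific
    nascent-RNA coverage with RPKM thresholds; integrates replication-timing
    tracks (Repli-seq scores, Repli-chip probe ratios) including late-segment
    classification and transcription-stratified timing distributions; builds
    percent-coordinate (metagene) profiles of CNV placement and relative
    replication timing along transcription units; and ships a fully
    parameterized synthetic-data generator so every stage is testable end to
    end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    mclust,
    jsonlite
Suggests:
    rtracklayer,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
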