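Package: valleycall
Title: Bimodal H3K27ac Valley Enhancer Calling and FGF Response Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies putative enhancers as low-signal valleys between
    bimodal H3K27ac peak pairs while excluding H3K27me3-marked regions,
    compares enhancer repertoires between conditions with a 0 bp gap rule,
    assigns enhancers to the nearest transcription start site and genomic
    context, aggregates read-density metaprofiles and motif-centred
    signal heatmaps with k-means clustering, scans sequences with
    position weight matrices using exact score-distribution thresholds,
    tests motif enrichment against shuffled-sequence nulls, scans
    ortholog sets for clusters of conserved 8-mers, and classifies
    direct versus indirect signalling targets from multiplexed
    count data using a cycloheximide contrast. Ships a fully seeded
    synthetic-data generator with recorded ground truth so every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    IRanges,
    GenomicRanges,
    igraph,
    optparse
Config/testthat/edition: 3
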