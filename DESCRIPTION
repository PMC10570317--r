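Package: stressgcn
Title: Stress-Responsive Gene Co-Expression Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An integrated co-expression-network workflow for identifying
    candidate key genes in multi-condition stress RNA-seq experiments.
    Calls differentially expressed genes per condition and time point with
    a negative-binomial Wald test, builds per-condition gene co-expression
    networks by thresholded Pearson correlation, merges them into
    integrated stress networks, reconstructs transcription-factor-centred,
    GO-filtered core networks with degree-based hub ranking, and profiles
    core genes with Z-scores and clustering. Ships a synthetic multi-stress
    count simulator with planted co-expression modules, hub transcription
    factors and differential expression, so every stage is testable against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    pheatmap,
    stats,
    utils,
    grDevices,
    grid,
    tools,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
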