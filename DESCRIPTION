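Package: mlnalign
Title: Local Alignment of Multilayer Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Local network alignment for multilayer (multiplex) networks. Two
    multilayer networks and a set of seed node similarities are merged into a
    weighted multilayer alignment graph whose vertices are matched node pairs
    and whose edges encode joint adjacency (homogeneous match/mismatch/gap
    within layers, heterogeneous match/mismatch across layers). Communities
    mined on the alignment graph yield local alignments, which are scored with
    multilayer extensions of F-score node correctness (F-NC) and the combined
    node-coverage/edge-conservation measure NCV-GS3. Includes a synthetic
    multilayer benchmark generator and a noise-degradation experiment driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    igraph,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
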