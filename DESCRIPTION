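Package: socialsync
Title: Sliding-Window Phase Synchrony Analysis of Social Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for dynamic functional connectivity between
    regions of interest during naturalistic video viewing. Computes
    sliding-window phase-locking values from band-limited instantaneous
    phases, residualizes nuisance signals at the volume and window level,
    runs edge-wise repeated-measures ANOVA across social-behavior
    conditions, builds thresholded networks with degree and eigenvector
    centrality, and contrasts clip-onset-aligned synchrony time courses.
    Includes a synthetic-session generator with controllable phase
    coupling so every stage is verifiable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse
Config/testthat/edition: 3
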