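Package: cortiwave
Title: Propagating Cortical Wave and Network-State Analysis for
    Micro-ECoG Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for multichannel micro-electrocorticography
    recordings on regular electrode grids: band-specific Butterworth
    filtering and Hilbert phase extraction for stationary (globally
    phase-locked) oscillations, voltage-threshold extraction of epileptic
    spike events, cross-correlation time-delay matrices and delay maps
    that reveal plane-wave and spiral propagation, PCA plus k-means
    classification of propagation patterns with elbow-based cluster-number
    selection, high-gamma cross-correlation functional connectivity with
    modularity-based network-state detection, and chi-squared / Cramer's V
    association analysis between network states and propagation types.
    Includes a synthetic-recording generator with full ground truth
    (stationary oscillations, plane waves, spirals, seizure spike trains,
    common-mode background, planted high-gamma connectivity blocks) so
    every stage is verifiable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
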