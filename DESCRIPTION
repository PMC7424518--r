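Package: chronnets
Title: Chronological Networks for Spatiotemporal Event Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Transforms time-ordered streams of georeferenced events into
    weighted graphs ("chronnets") whose links count chronologically
    consecutive events between grid cells, and mines those graphs for
    frequent patterns, outlier cells, spatiotemporal clusters and change
    points. Includes readers for delimited event tables and the MODIS
    MCD14ML active-fire dialect, rectangular gridding plus analytic
    utilities for icosahedral hexagonal global grids, network
    characterization (degree and strength distributions, heavy-tail
    fitting, centralities, transitivity, path statistics), community-based
    event clustering with label smoothing and change-point detection, and
    a seed-deterministic synthetic event generator (probability-matrix
    emission, alternating Gaussian bursts, multi-period regimes, sampled
    Lorenz and Roessler trajectories).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    deSolve,
    mclust,
    geosphere,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
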