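Package: netmfa
Title: Reliable Multi-Fractal Analysis of Weighted Complex Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the multi-fractal spectrum of weighted undirected
    networks with finite metric resolution. Implements box-covering (via
    greedy coloring of the dual graph) and randomized sandbox estimators of
    the generalized dimension D(q), together with a data-driven critical-scale
    filter and scaling-range localization that remove the staircase bias the
    discrete shortest-path support induces in log-log regression. Includes
    deterministic generators for weighted Sierpinski and (u,v)-flower fractal
    network families with known theoretical dimensions, link-weight skewness
    diagnostics, exponential-versus-power-law model selection for small-world
    classification, and a per-node localized scaling feature space for
    label-free network community detection.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
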