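Package: gbcpop
Title: Population Modeling of Globular Bushy Cells by Adaptive Coincidence
    Counting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates globular bushy cells (GBCs) of the anteroventral
    cochlear nucleus as adaptive coincidence counting neurons driven by
    auditory-nerve spike trains. Provides a phenomenological auditory-nerve
    surrogate generator, spike-train response measures (spontaneous and
    driven rates, modified coefficient of variation, vector strength,
    entrainment index), peristimulus time histogram shape classification
    (primary-like-with-notch and onset-L detection with chopper and dipper
    rejection), six-dimensional parameter-grid screening with dimensional
    stacking, frequency-response-area analysis, and parameter-space analyses
    (grid connectivity, convexity by interpolation, pairwise parameter
    correlations, and polynomial input-output variance decomposition).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
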