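Package: thermocm
Title: Cross-Mapping Analysis of Autonomic and Facial Skin Temperature
    Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies nonlinear coupling between autonomic nervous system
    correlates (heart rate variability, tonic electrodermal activity) and
    facial skin temperature time series using delay embeddings and
    convergent cross mapping. Provides preprocessing of cardiac and
    electrodermal recordings (adaptive QRS detection, threshold-based RR
    artifact correction, piecewise cubic interpolation to a uniform grid,
    tonic/phasic decomposition), HRV and EDA feature extraction, embedding
    parameter selection by automutual information and false nearest
    neighbours, a nearest-neighbour cross-map estimator with exponential
    distance weights, block permutation inference, two-stage false
    discovery rate control, split-plot analysis of variance, and seeded
    synthetic generators with known coupling structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    deSolve,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
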