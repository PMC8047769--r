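Package: ddasim
Title: In Silico Development of Data-Dependent Acquisition Strategies for LC-MS/MS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A virtual liquid-chromatography tandem mass spectrometer for
    prototyping and optimizing data-dependent acquisition (DDA) strategies on
    synthetic chemical mixtures with known ground truth. Implements the TopN
    controller with a dynamic exclusion window, a weighted dynamic exclusion
    generalization (WeightedDEW), and a region-of-interest tracking controller
    (SmartROI) with shifted scheduling; computes the theoretical upper bound on
    fragmentation coverage for a run via bipartite maximum matching
    (Hopcroft-Karp); and scores acquisition runs against picked-peak bounding
    boxes by coverage and efficiency, including grid search over controller
    parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    mzR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
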