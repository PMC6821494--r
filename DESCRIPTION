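Package: spinecalcium
Title: Analysis of Dendritic Spine Calcium Imaging Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trace-level analysis of calcium fluorescence signals recorded
    from dendritic spines, dendritic shaft segments and the soma during a
    behavioural task. Provides SWC morphology handling with traversal and
    Euclidean distances, baseline and photon shot-noise estimation,
    probabilistic estimation of activity independent of a global
    (back-propagating action potential) reference, removal of the bAP
    component by reference deconvolution and kernel fitting (plus four
    alternative subtraction methods), trial-epoch selectivity statistics
    with permutation and bootstrap inference, distance-resolved pairwise
    signal and noise correlations with exponential-linear fitting, and a
    spike-to-fluorescence forward simulator with distance-dependent
    correlated Poisson inputs used to validate every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    igraph,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
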