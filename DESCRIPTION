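Package: mcnet
Title: Morphological Correlation Networks for Landmark-Based Modularity
    Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects variational modules in landmark-based morphometric
    data with morphological correlation networks. Configurations are
    superimposed by generalized Procrustes analysis on reference
    landmarks, the fitted similarity transforms are transferred to
    measurement points, pairwise Escoufier Rv coefficients between
    measurement-point coordinate blocks are assembled into a thresholded
    weighted network, and modules are extracted by minimizing a
    Reichardt-Bornholdt spin-glass Hamiltonian with repeated simulated
    annealing, reporting distinct solutions with occurrence frequencies.
    Includes Procrustes ANOVA for digitization error, threshold-sweep and
    leave-one-out robustness analyses, and a synthetic generator of
    landmark datasets with planted modular covariance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
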