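Package: sexratiosim
Title: Virtual-Ecologist Simulation of Sex-Ratio Sampling Bias
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Individual-based simulation of how passive capture methods
    (fixed trap transects) and active searches (daily random transects with
    sex-specific detectability) estimate the sex ratio of a closed population
    whose true ratio is 1:1. Males and females move on a bounded lattice with
    complementary per-step movement probabilities and an inverse-distance
    dispersal kernel; captures follow mark-recapture semantics (each
    individual counted once per method) and every replicate is classified as
    male-biased, female-biased or unbiased by a chi-square goodness-of-fit
    test against the equal split. Includes single-parameter sensitivity
    sweeps, effort-by-asymmetry interaction sweeps, CSV export of the sweep
    tables, and summary figures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
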