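Package: sensewin
Title: Sensitive-Period Analysis of Exposure Timing with Conditional
    Inference Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Random-forest regression with conditional inference trees for
    identifying sensitive developmental periods: which years of exposure to
    childhood adversity best predict a continuous regional brain signal.
    Provides a conditional-inference tree base learner with permutation-test
    variable selection, a subsampled forest with out-of-bag bookkeeping,
    permutation (MSE-increase) variable importance, a re-randomization
    (response-reshuffling) significance test for peak and combined-window
    importance with Benjamini-Hochberg FDR correction, eigenvariate
    extraction from cluster voxel matrices, and a seeded synthetic cohort
    generator that emulates annual binary exposure histories and
    maltreatment-type indicators for fully reproducible testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
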