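Package: redgem
Title: Reduced Genome-Scale Metabolic Models and Constraint-Based Flux Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, reducing and interrogating constraint-based
    metabolic models. Implements model reduction (dead-end and blocked-reaction
    pruning, reaction lumping, biomass-precursor producibility checks, greedy
    gap filling, and detection/correction of thermodynamically infeasible
    cycles), flux balance analysis with a two-step objective-then-L1-norm
    optimization, shadow-price sensitivity analysis, flux variability analysis,
    coordinate hit-and-run flux sampling with rounding, and squared-error
    validation of predictions against measured exchange rates. Ships
    experimental exchange-rate datasets for Streptomyces clavuligerus
    cultivations and a synthetic network generator with known ground truth for
    end-to-end testing of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    boot,
    withr
Config/testthat/edition: 3
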