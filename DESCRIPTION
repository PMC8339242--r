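Package: hawkdove
Title: Size-Based Decision Theory of Animal Conflict
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative decision theory for two-player animal conflict based on
    body size. Computes the four size-based interaction descriptors (mutualism,
    antagonism, aggression, altruism) and the antagonism-relativized hawk-dove
    reward matrix for a dyad, solves the analytic break-even thresholds that
    separate cooperative from aggressive best responses (golden-section threshold,
    hawk shift, Fibonacci retracement mark, surrender point), and predicts each
    player's optimal strategy. Validates the descriptors against empirical
    interaction strengths derived from paired co-culture/monoculture growth
    trajectories, with Gompertz, logistic and Richards growth-curve fitting,
    model selection and growth-phase partitioning. Builds trait-based social
    networks (mutualism, antagonism, aggression, altruism) and a SNP relatedness
    network over a cohort, assigns hierarchy roles, and tests tier body-mass
    ratios against the decision-model thresholds. Includes seeded generators for
    trait cohorts, coupled-logistic co-culture trajectories and full-sib
    genotypes so the whole pipeline can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    minpack.lm,
    deSolve,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
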