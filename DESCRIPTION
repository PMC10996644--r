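Package: patchforage
Title: Simulation and Model-Based Analysis of Patch-Foraging Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying patch-leaving decisions in depleting-patch
    foraging tasks. Implements an inhomogeneous gamma process reward
    simulator (exponentially decaying Poisson event rate with every L-th
    event observable as a fixed-volume reward), synthetic session
    generation from known agent policies, preprocessing of session logs
    (inclusion filters, task-relevant travel and residence estimation,
    time-on-task detrending), heuristic and marginal-value-theorem
    patch-leaving models, maximum-likelihood and maximum-a-posteriori
    estimation of the reward-rate parameters with gamma priors,
    threshold-crossing predictive models, and evaluation machinery
    (hierarchical cluster bootstrap, rate-estimation-error regression,
    cross-validated model comparison with bootstrap confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
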