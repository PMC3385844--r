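Package: armdyn
Title: Dynamical Modelling of Arm Function and Use After Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and analyses a first-order nonlinear state-space model of
    upper-extremity recovery after stroke, in which normalised arm function
    (from Wolf Motor Function Test time scores) and spontaneous arm use (from
    Motor Activity Log Amount of Use ratings) evolve on a 4-month grid and
    drive one another. Candidate update rules for function and use are fitted
    per subject by Bayesian evidence maximisation (empirical-Bayes linear
    regression with nonzero-mean Gaussian priors), compared with Bayes factors
    and group-level positive evidence ratios, and evaluated by leave-one-out
    trajectory prediction against a randomized baseline. The coupled map's
    fixed points, saddle-node limit points and bistable regimes are computed
    directly. A synthetic-cohort generator emulating the clinical visit
    schedules supports surrogate-data validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
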