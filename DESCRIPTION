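Package: udsamp
Title: Simulation and Analysis of Uncertainty-Driven Sampling in Word Learning
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse experiments in which participants
    learn novel word-object associations, judge their own knowledge of each
    label, choose a small number of objects to hear again (the sampling
    phase), and are then tested with binary confidence ratings. Provides a
    generative simulator of the full design (knowledge judgements, weighted
    sampling without replacement, test accuracy and confidence, plus
    familiar/unfamiliar control judgements), logistic mixed-model fitting
    with crossed random effects, a within-participant permutation test for
    the two-column sampling-matrix model, a chance-corrected sampling
    statistic analysed with beta regression, likelihood-ratio and Wald
    tests, parametric bootstrap confidence intervals, and an end-to-end
    pipeline that turns a data directory into per-group analysis reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
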