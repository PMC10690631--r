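Package: gravicept
Title: Gravity-Prior and Optical Models of Interceptive Timing for Looming Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for modelling the timing of manual interception of
    vertically approaching (looming) targets. Builds the target kinematics of
    a virtual free-fall scene (accelerated, constant-velocity and decelerated
    profiles matched on mean velocity), computes arrival-time predictors based
    on an internal model of gravity engaged at different times after motion
    onset and on a known-size (KS) optical looming model, simulates trial-level
    button-press responses from a hierarchical generative model, and analyses
    them with repeated-measures ANOVA and Bayesian linear mixed regressions
    (Gibbs sampling via JAGS), including Bayesian R-squared, an engagement-time
    scan, and PSIS-LOO model comparison.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rjags,
    coda,
    car,
    MASS,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
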