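Package: statkin
Title: Mechanistic Models and Likelihood-Free Inference of STAT1/STAT3
    Signalling Kinetics at IL-6 and IL-27 Receptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action ordinary differential equation models of receptor
    assembly and STAT1/STAT3 competition downstream of HypIL-6 and IL-27,
    including chimeric and Y613F receptor variants and two receptor
    internalization hypotheses.  Provides a synthetic flow-cytometry
    time-course generator with the study design (replicates, STAT antibodies,
    time points, cytokines, cell types, linear background fluorescence),
    preprocessing (background subtraction and reference-point normalization),
    approximate Bayesian computation with sequential Monte Carlo (ABC-SMC)
    for joint model selection and two-stage parameter inference, model-based
    predictions (dose-response curves, receptor-variant simulations,
    receptor/STAT abundance scans), and estimators of two-dimensional
    membrane dissociation constants from single-molecule co-tracking counts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
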