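Package: panelmsm
Title: Continuous-Time Multistate Markov Models for Panel-Observed
    Cognitive Ageing Data
Version: 0.1.0
Authors@R: person("panelmsm", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Fits continuous-time multistate Markov models to
    panel-observed transitions between no cognitive impairment, cognitive
    impairment without dementia, dementia, and death, with proportional
    covariate effects on transition intensities and a piecewise-constant
    age dependency.  Includes maximum-likelihood estimation via the
    interval-censored panel likelihood (with optional exactly observed
    death times), Hessian-based standard errors, hazard-ratio tables,
    state-occupancy and prevalence curves, expected total length of stay,
    sojourn times, a synthetic cohort generator emulating the structure of
    an English Longitudinal Study of Ageing style panel, and a
    command-line pipeline (simulate / fit / derive / gof).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
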