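Package: qbdoe
Title: Quality-by-Design Experiment Design and Bayesian Optimization for
    Formulation Development
Version: 0.1.0
Authors@R:
    person("qbdoe", "developers", role = c("aut", "cre"),
           email = "qbdoe@example.org")
Description: Tools for quality-by-design optimization of pharmaceutical
    formulations: screening and response-surface experimental designs
    (Plackett-Burman, blocked central composite), full quadratic
    response-surface models with lack-of-fit ANOVA, Derringer-Suich
    desirability optimization, Gaussian-process Bayesian optimization
    with Matern 3/2 kernels and Expected Improvement / Confidence Bound
    acquisitions, a synthetic experiment simulator for closed-loop
    testing, and closed-form in-vitro/in-vivo evaluation metrics (MTT
    viability, apparent permeability, intrinsic dissolution rate,
    non-compartmental pharmacokinetics with relative bioavailability).
    Ships a co-milled celecoxib formulation case study as packaged
    fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
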