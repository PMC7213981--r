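Package: nicddrain
Title: Binding-Site-Coupled Degradation Kinetics of the Notch
    Intracellular Domain
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Deterministic and stochastic models of nuclear Notch
    intracellular domain (NICD) turnover coupled to occupancy of Su(H)
    paired binding sites (SPS), where DNA-bound NICD is phosphorylated by
    the Cdk8 kinase module and routed to fast degradation. Provides a
    partition-function model of site occupancy, steady-state and dynamic
    solutions of the kinetic equations, closed-form linear-regime analysis
    (titration slopes, effective endogenous site number, phosphorylation-
    rate estimation), an exact event-driven stochastic simulator used as
    an independent oracle, regression-based inference for reporter
    titration data with delta-method error propagation, Hill-function
    decay fitting for protein half-life estimation, and seeded synthetic
    data generators for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
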