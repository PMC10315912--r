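Package: t2dmsim
Title: Deterministic Compartmental Projection of Type 2 Diabetes Burden and
    Prevention Interventions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A deterministic compartmental (ODE) model of type 2 diabetes
    mellitus among adults aged 20-79, stratified by sex, twenty 3-year age
    bands, the eight-way lattice of obesity, physical inactivity and smoking,
    diabetes status, and intervention-coverage class. Includes a synthetic
    baseline-target generator encoding published Qatari burden anchors,
    nonlinear least-squares calibration of natural-history parameters,
    twelve public-health intervention scenarios plus two combination
    packages (lifestyle management, active commuting, dietary, and
    subsidy/taxation interventions), a bisection solver that drives obesity
    prevalence to stated scenario endpoints, a BMI-distribution-shift
    utility, and a counterfactual outcome engine reporting prevalence,
    annual new cases, and cumulative and proportional averted cases over
    2021-2050.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
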