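Package: allocamp
Title: Kinetic Modelling of Allosteric Modulation of CB1-Mediated cAMP
    Signalling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a unified kinetic model of the cannabinoid CB1
    receptor under co-treatment with an orthosteric agonist and the
    allosteric modulator ORG27569, including a transitional ternary
    receptor state that internalises but does not signal. Provides
    time-course simulation with timed dosing schedules, an EMAX coupling
    of receptor-mediated inhibition to forskolin-driven cAMP turnover,
    kinetic-lag statistics for the delayed disinhibition of cAMP
    (model-predicted tolerance crossing and plateau-followed-by-one-phase
    association fits), parameter-uncertainty propagation by
    multivariate-normal sampling with prediction bands and coverage
    checks, probe-dependence analysis across agonists with grid
    calibration of the modulator association rate, and a generator of
    synthetic CAMYEL-style BRET plate datasets for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    MASS,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
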