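Package: amyloidcycle
Title: Vicious-Cycle Kinetic Modelling of Amyloid-Beta Accumulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modelling age-dependent accumulation of soluble
    amyloid-beta (Abeta42) in the Tg2576 mouse brain with a two-variable
    kinetic model in which Abeta and an abstract disease factor X drive
    each other's production through Hill-type positive feedback (a
    "vicious cycle").  Provides the logistic reference curve for the
    mouse time course, stiff integration of the coupled rate equations,
    fitting of the kinetic parameters to a target series by summed
    absolute log-ratio minimisation, in-silico single and combination
    interventions with minimum-effective-dose searches, iso-effect
    contours and optimal dose combinations, and fixed-point/stability
    analysis of the underlying dynamical system.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
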