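Package: levarc
Title: Levetiracetam Dosing Simulations in Augmented Renal Clearance
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population pharmacokinetic simulation of intravenous
    levetiracetam in critically ill patients with augmented renal clearance.
    Implements a two-compartment infusion model with a creatinine-clearance
    covariate on clearance in closed form, lognormal inter-individual
    variability, Monte Carlo virtual-patient generation, and
    probability-of-target-attainment evaluation of intermittent,
    extended-infusion and continuous-infusion regimens against the 12-46
    mg/L trough reference range, including loading-dose time-to-target
    analyses and regression against the published attainment grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
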