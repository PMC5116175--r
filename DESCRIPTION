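Package: milkpk
Title: Population Pharmacokinetics of Drug Depletion in Plasma and Milk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the depletion of long-acting veterinary
    drugs in the plasma and milk of lactating animals. Implements a
    two-compartment disposition model with first-order subcutaneous
    absorption and a cumulative milk-excretion compartment (closed form and
    ODE), noncompartmental analysis (lambda-z, trapezoidal AUC), FOCE-type
    nonlinear mixed-effects population estimation with exponential
    inter-individual variability and additive/proportional/combined residual
    error, nonparametric subject bootstrap, Monte Carlo population
    simulation, and percentile-band withdrawal-time estimation against an
    assay detection limit. Ships transcriptions of published goat
    tulathromycin average concentration data and population parameter
    estimates as fixtures, plus a synthetic study generator emulating the
    source sampling designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
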