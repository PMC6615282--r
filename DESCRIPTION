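Package: ecmopk
Title: Population Pharmacokinetics of Sufentanil During Venoarterial ECMO
Version: 0.1.0
Authors@R: person("ECMO PK", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for population pharmacokinetic analysis of continuous
    intravenous sufentanil infusion in critically ill adults supported with
    venoarterial extracorporeal membrane oxygenation (VA-ECMO). Implements a
    closed-form two-compartment infusion model with covariate effects of body
    temperature on clearance and total plasma protein on peripheral volume,
    first-order conditional estimation with interaction (FOCE+I) for nonlinear
    mixed-effects fitting, stepwise covariate selection by likelihood-ratio
    criteria, non-stratified bootstrap and prediction-corrected visual
    predictive checks for model evaluation, Monte Carlo dosing simulations over
    covariate grids, and a synthetic-cohort generator reproducing the sparse
    ICU sampling design so that every pipeline stage is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
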