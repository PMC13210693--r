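Package: ruvdiag
Title: Residual Error Coding and Diagnostic Residuals for Nonlinear
    Mixed-Effects Pharmacokinetic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to study how the diagnostic scaling factor W used in
    NONMEM-style residual error blocks affects individual weighted residuals
    (IWRES) while leaving the likelihood-based diagnostics (WRES, CWRESI)
    unchanged for simple error models. Provides a closed-form one-compartment
    first-order oral absorption model with analytic random-effect
    sensitivities, stochastic simulation of population pharmacokinetic
    datasets under additive, proportional and combined residual error, a
    first-order conditional estimator with interaction (FOCE-I) supporting
    nine residual-error coding variants, the full set of NONMEM-style
    diagnostic residuals (PRED/RES/WRES, IPRED/IRES/IWRES, CWRESI),
    epsilon-shrinkage, pairwise run comparisons with implicit-W
    back-calculation, and a nine-run study orchestrator with figure-ready
    data export.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
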