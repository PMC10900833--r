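Package: krtdose
Title: Monte Carlo Beta-Lactam Dose Optimization for Kidney Replacement Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates one-week plasma concentration-time profiles of five
    beta-lactam antibiotics (cefepime, ceftazidime, imipenem, meropenem,
    piperacillin with tazobactam) in virtual critically-ill, anuric patients
    receiving five kidney replacement therapy (KRT) schedules. A
    one-compartment, first-order model with piecewise-constant extracorporeal
    clearance (saturation/sieving coefficient times effluent flow) is solved
    analytically per event segment. Per-day probability of target attainment
    (fT>MIC and fT>MICx4) and neurotoxicity-threshold exceedance are estimated
    over cohorts drawn from truncated log-normal parameter distributions, and
    an optimal-regimen selection rule picks the smallest daily dose attaining
    the target in at least 90 percent of patients.
License: MIT + file LICENSE
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
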