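Package: pdcycle
Title: Kinetics of Phosphorylation-Dephosphorylation Cycles with
    Kinase-Phosphatase Complex Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action kinetic models of phosphorylation-dephosphorylation
    cycles (PDCs), including the extension in which the antagonistic kinase
    and phosphatase form a physical complex with kinase and/or phosphatase
    activity.  Provides the exact steady-state solution of the basic cycle
    (a cubic in the kinase-substrate complex), asymptotic phosphorylation
    limits, Hill numbers via the response-coefficient formula corrected for
    partial asymptotic phosphorylation, stiff ODE integration and numeric
    steady states for the extended models, a total quasi-steady-state
    (tQSSA) reduction of the phosphatase-active variant, dose-response
    sweeps with bell-shape metrics and 2-D parameter scans, and transient
    scenarios for phosphoinositide regulation on endosomes (linear kinase
    recruitment and a triggered kinase-to-phosphatase activity switch).
    All results are returned as tibbles and compose with the tidyverse.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
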