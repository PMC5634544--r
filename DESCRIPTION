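Package: easleep
Title: Energy Allocation Model of Sleep-Wake Energetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulator for the energy allocation model of sleep: a two-phase
    (wake/sleep) nonautonomous ordinary differential equation for biological
    debt, Poincare-map limit-cycle analysis with saddle-node bifurcation
    detection, and a three-strategy protocol that quantifies daily energy
    savings from state-dependent metabolic partitioning (MAI), metabolic
    rate reduction during sleep (rho), sleep quota (TST), and circadian
    amplitude. Includes parameter sweeps over these four variables, a
    sensitivity grid over the price and circadian-level constants, and
    multi-day sleep-restriction runs with steady-state diagnostics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
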