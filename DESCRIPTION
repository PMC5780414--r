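Package: darkcarbon
Title: Dark Bicarbonate Assimilation and Prokaryotic Carbon Budgets for the
    Deep Water Column
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Radiotracer and respiration rate calculus for aphotic
    (meso- and bathypelagic) microbial carbon budgets. Converts raw
    [3H]-leucine and [14C]-bicarbonate incubation counts into prokaryotic
    heterotrophic production (PHP) and assimilation of bicarbonate in the
    dark (ABD), electron-transport-system (ETS) assays into prokaryotic
    respiration (PR) with Arrhenius temperature correction, and derives
    community metrics (carbon demand, growth efficiency, cell-specific
    rates, generation times). Integrates rate profiles over the dark water
    column by the trapezoidal rule with bottom extension, aggregates
    stations into basin reports with dark-to-photic production ratios, and
    ships a forward campaign simulator for parameter-recovery testing plus
    a bundled deep Mediterranean station fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
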