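Package: abxcarbon
Title: Greenhouse-Gas Emissions Accounting for IV Antimicrobial Single-Use Waste
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates carbon-dioxide-equivalent greenhouse-gas emissions from the
    single-use disposable waste generated by packaging, preparing, and administering
    intravenous antimicrobials in hospitals. Items are weighed, classified to EPA
    Waste Reduction Model (WARM) material types, and multiplied by disposal-pathway
    emission factors; per-dose and per-day-of-therapy (DOT) factors are averaged
    across measurement sites and across drug products of each agent. Provides DOT,
    dose, and drug-product calculators that convert antimicrobial-use line listings
    into emissions reports with interpretable equivalencies (miles driven, gasoline
    consumed, and others), a disposal-scenario mechanism (landfill, recycling,
    combustion overrides per material), a seeded synthetic inventory generator, and
    an importer for institution-supplied reference tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
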