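Package: safskin
Title: Supercritical Antisolvent Fractionation Yields, Response-Surface
    Optimization, and Compartmental Skin Permeability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing supercritical antisolvent fractionation
    (SAF) experiments and for screening the skin penetration of the
    recovered antioxidants. Covers mass-balance arithmetic for extraction
    and fractionation yields and enrichment ratios, two-factor central
    composite designs with quadratic response-surface fitting and
    Derringer-Suich composite-desirability optimization of pressure and
    CO2 flow rate, and a compartmental series-parallel resistance model of
    epidermal permeability with pathway analysis and safety
    classification. Ships the 13-run pilot-plant dataset and the
    resistance profiles of caffeic, chlorogenic and ferulic acid as
    plain-text fixtures, plus seeded generators for synthetic response
    surfaces and resistance profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
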