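Package: riverstoich
Title: Nutrient Stoichiometry Assessment for River-Mouth Monitoring Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to assess dissolved inorganic nitrogen, total phosphorus
    and dissolved silica stoichiometry in river-mouth water-chemistry
    monitoring records. Converts mass concentrations to molar units, computes
    Redfield-scaled ternary percentages and nutrient-depletion zones, Carlson
    trophic state indices for the depleted nutrient, the index of coastal
    eutrophication potential (ICEP), critical nitrogen and phosphorus
    concentrations derived from silica levels, and exceedance ratios.
    Includes the sample-to-monthly-to-overall aggregation ladder used in
    coastal monitoring programmes, quality-control retention rules, a
    synthetic monitoring-data generator for testing, and plotting helpers
    for ternary and exceedance diagrams.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
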