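Package: scoscreen
Title: Screening Yeasts for Single-Cell Oil: Fatty-Acid Profiles,
    Biodiesel Properties, Growth Kinetics and PCR-RFLP Typing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computational toolkit for screening oleaginous yeasts as
    single-cell-oil (SCO) feedstocks. Parses relative fatty-acid
    composition tables and classifies acids by unsaturation; predicts
    biodiesel fuel properties (unsaturation degree, cetane number, mean
    chain length, low calorific value, flash point, kinematic viscosity)
    from fatty-acid methyl ester profiles; computes specific growth
    rates, generation times, volumetric productivities and lipid content
    from culture records and optical-density time series; and performs
    in-silico PCR-RFLP typing of ITS amplicons against a reference
    fragment-pattern database. Includes seeded generators for
    compositional profiles, growth curves and sequences with planted
    restriction sites, and packaged fixtures for a seven-strain kefir
    yeast screen.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
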