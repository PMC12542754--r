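Package: springcarb
Title: Radiotracer Carbon Metabolism Rates and Aqueous Speciation for
    Acidic Hot Springs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying microbial carbon metabolism in acidic
    geothermal springs from in situ radiotracer (14C) microcosm assays,
    together with the aqueous geochemistry needed to interpret them.
    Converts liquid scintillation counts to disintegration rates via a
    quench curve, estimates zero-order carbon assimilation and
    dissimilation rates normalised to solid-phase carbon with full
    first-order uncertainty propagation, and contrasts light and dark
    incubations. Resolves measured hot-spring water compositions into
    chemical species using temperature-dependent dissociation constants
    and extended Debye-Huckel activity coefficients, computes the charge
    imbalance of an analysis as a percent of mean charge, and solves for
    the charge-balance pH. Also derives stable-isotope fractionation
    (capital-delta 13C between biomass and dissolved inorganic carbon)
    and molar C:N ratios with propagated errors, and simulates complete
    synthetic microcosm experiments with Poisson counting noise so that
    the full estimation pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
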