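Package: lymphtrial
Title: Genetic Subtype-Guided Trial Analysis for Relapsed/Refractory DLBCL
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for rule-based genetic subtyping of diffuse large B-cell
    lymphoma (DLBCL) from targeted mutation panels and BCL2/BCL6/MYC FISH
    calls, subtype-guided regimen assignment, Simon two-stage phase II
    design computation by exact binomial enumeration, and trial endpoint
    statistics (response rates with exact confidence intervals,
    Kaplan-Meier estimation, log-rank comparison, univariate Cox
    regression for binary biomarkers). Includes a seeded synthetic cohort
    generator with genotype-stratified arms so the full pipeline can be
    exercised and calibrated without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
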