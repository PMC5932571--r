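Package: larvatk
Title: Toxicokinetic Modelling of Waterborne Drug Exposure in Zebrafish Larvae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compartment-model toxicokinetics for waterborne chemical exposure
    of zebrafish (Danio rerio) larvae. Implements one-compartment and
    eye/rest-of-body multi-compartment uptake-elimination models with
    closed-form and numerical solutions, rate-constant estimation from
    time-course data, a passive-partitioning (gill-uptake) prediction
    baseline, biphasic depuration half-life analysis, tissue-distribution
    statistics, four-parameter logistic dose-response fitting with
    internal-dose conversion, and seeded synthetic-data generators that
    emulate the experimental designs the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
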