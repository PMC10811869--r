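Package: esmsoc
Title: Equivalent Soil Mass Accounting for Soil Organic Carbon Stocks and Crediting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes soil organic carbon (SOC) stocks from layered bulk-density and
    carbon-concentration profiles on a fixed-depth (FD) and an equivalent-soil-mass
    (ESM) basis, including a cumulative-mass cubic-spline ESM and a classical
    mass-correction ESM. Provides change statistics between two sampling times
    (Welch t, confidence intervals, Hedges' g), attribution of the FD error to
    bulk-density change, and carbon-credit issuance under an empirical-sampling
    lower-confidence-limit rule. A seeded generator of synthetic two-time-point
    profile sets emulating long-term cropping-system trials makes every stage
    testable without field data.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
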