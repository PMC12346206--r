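Package: dhicost
Title: Cost-of-Illness Modelling for Diabetic Hand Infections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reproducible pipeline for bottom-up cost-of-illness analysis
    of surgically treated diabetic hand infections. Provides a synthetic
    patient-cohort generator calibrated to a published 75-patient case
    series, direct and indirect (human-capital) cost aggregation, a
    three-step currency and CPI inflation adjustment to Q4-2022 US dollars,
    a Monte Carlo cost simulator with probabilistic sensitivity analysis
    over triangular, normal, uniform and beta input distributions, and
    tie-corrected Kruskal-Wallis comparisons of visits and costs across
    surgical-intervention groups, with a permutation alternative.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
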