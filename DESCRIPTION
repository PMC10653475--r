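Package: obprotect
Title: Market-Exclusivity Analytics for Orange Book-Listed Insulin Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for longitudinal market-exclusivity analysis of
    FDA-approved insulin products. Reads Orange Book-style delimited listings
    (products, patents, regulatory exclusivities) together with curated patent
    annotations, applies cohort inclusion rules for biosynthetic insulins,
    classifies patents by filing timing and device status, computes
    last-to-expire durations of expected protection at the product and
    insulin-line level, quantifies the added protection from device patents
    (including device patents that never mention the active ingredient), and
    runs a follow-on-entry sensitivity analysis for 505(b)(2) competitors.
    Includes a seeded synthetic cohort generator with recorded ground truth so
    every stage is testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
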