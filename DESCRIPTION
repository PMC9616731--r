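Package: foragecog
Title: Lab-to-Field Analysis of Bumblebee Short-Term Memory and Foraging
    Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for linking radial-arm-maze (RAM) short-term-memory assays
    of bumblebees to their subsequent real-world foraging performance.
    Provides win-shift error scoring of maze visit sequences, Monte-Carlo
    validation of maze performance against per-bee movement-rule nulls built
    from empirical arm-to-arm transition matrices, conversion of RFID reader
    and nest-scale event logs into per-trip nectar and pollen efficiency
    records, ordered-quantile normalization, composite weather scores, and an
    information-theoretic (delta-AIC/AICc) mixed-model selection protocol for
    seasonal analyses. A synthetic-data generator reproduces the statistical
    structure of the field study (memory-limited maze agents, staggered
    colony design, scale noise, week-correlated weather) so the full pipeline
    is testable without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    mgcv,
    survival,
    jsonlite,
    readr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
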