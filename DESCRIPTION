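Package: hwdsens
Title: Sensitivity Analysis of Heat Wave Definitions for Heat-Related Illness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to compare competing heat wave definitions against daily
    heat-related-illness surveillance counts. Derives regional daily heat
    metrics (relative humidity via the Magnus formula, maximum apparent
    temperature via the NWS Rothfusz heat-index algorithm), flags heat wave
    days under a configurable definition grammar (metric x duration x
    threshold type x intensity, including the standard 28-definition set),
    fits offset-adjusted negative binomial regressions of daily counts on
    each definition's flags, ranks definitions by AIC, and compares flagged
    days with National Weather Service heat alerts using the McNemar test.
    Includes a seeded synthetic-data generator (seasonal AR(1) weather,
    sparse alerts, negative-binomial counts with surveillance censoring) so
    the full pipeline is testable without restricted surveillance data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
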