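Package: carenet
Title: Collaboration Networks and Staffing Intensity from EHR Audit Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds health-care-worker (HCW) collaboration networks from
    electronic health record (EHR) audit logs, where two HCWs are linked
    whenever they act on the same patient's record on the same calendar day.
    Provides native eigenvector- and betweenness-centrality implementations
    with independent testing oracles, per-stay daily patient staffing
    intensity with a fractional length-of-stay denominator, propensity-score
    cohort matching, Mann-Whitney U comparison families with Bonferroni
    correction, a seeded synthetic audit-log simulator with planted team
    structure, and a one-call pipeline producing a reproducible report
    bundle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
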