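Package: p2i
Title: Portfolio-to-Impact Modelling of Health Product R&D Pipelines
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Deterministic, archetype-parameterized portfolio model for
    health product research and development. Estimates annual funding
    needs, expected candidate flow through preclinical to phase III,
    expected product launches over a calendar horizon, and the health
    impact (DALYs averted, deaths averted, economic value) of launches.
    Ships a parameter registry of per-phase development costs,
    probabilities of success, and cycle times for eleven product
    archetypes (vaccines, new chemical entities, repurposed drugs,
    biologics, diagnostics), a prospective/retrospective planner, a
    config-driven funding-scenario runner, and a Monte Carlo attrition
    simulator used to validate the deterministic engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
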