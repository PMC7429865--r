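Package: crewmet
Title: Metabolic Resource Budgets for Spaceflight Crews
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic models of astronaut metabolic resource utilization:
    energy expenditure, oxygen consumption, carbon dioxide and metabolic heat
    production, and hydration water requirements, at rest and during
    countermeasure exercise. Combines anthropometric scaling under geometric
    similarity (body mass from BMI, Du Bois body surface area), Harris-Benedict
    resting metabolic rate, Weir indirect calorimetry, partitional-calorimetry
    heat balance with a steady-state sweat-rate prediction, and renal/insensible
    water budgeting, then aggregates person-days to crew- and mission-level
    totals for life-support sizing studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
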