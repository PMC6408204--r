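Package: dietfootprint
Title: Carbon Footprint and Diet Quality of 24-Hour Recall Diets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Links 24-hour dietary recall records to commodity-level
    life-cycle greenhouse-gas emission factors (kg CO2-equivalents per kg)
    through recipe decomposition, with retail- and consumer-level loss
    adjustment; aggregates to per-person dietary carbon footprints and
    per-1000-kcal nutrient and food-pattern densities; scores diets on the
    12-component Healthy Eating Index 2010; ranks diets into survey-weighted
    footprint quintiles; and compares low- and high-footprint diets with
    design-based (Taylor-linearized) survey statistics, including domain
    t-tests, a Rao-Scott adjusted chi-square, sandwich-variance regression,
    and quintile trend tests. A synthetic-data generator emulating national
    dietary survey structure makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
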