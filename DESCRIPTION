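Package: hgexposure
Title: Dietary Mercury Exposure Assessment for Fish-Meal Intervention Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing dietary methylmercury exposure from fish
    consumption in intervention-style studies: descriptive summaries of fish
    tissue mercury by species and preparation state, per-subject intake
    arithmetic (estimated daily and weekly intake, normalised by body
    weight), risk characterisation against regulatory limits (PTWI, US-NRC
    weekly limit, maximum permitted concentrations in food), scenario
    projections for reference consumers, longitudinal blood and hair
    biomarker summaries with hair-to-blood ratios and linear fits, and a
    seeded synthetic-data generator that emulates the cohort, meal schedule,
    tissue concentrations and biomarker trajectories of a two-week
    fish-meal intervention so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
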