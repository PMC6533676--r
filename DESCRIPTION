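Package: gullteb
Title: Time-Energy Budgets of GPS/Accelerometer-Tracked Herring Gulls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify time-energy budgets of central-place foraging
    gulls from GPS tracking with tri-axial acceleration bursts. Segments
    foraging trips with centered-duration time accounting, classifies
    acceleration bursts into fine behaviors and four energetic classes,
    annotates movement modes by expectation-maximization binary clustering
    of speed and turning angle, assigns habitat from polygon layers with
    buffer and behavior-conditional rules, prices behavior time with an
    allometric metabolic model, tests habitat effects on energetic cost
    with mixed models, and computes daily-budget and prey-equivalent
    scenarios. A synthetic-data generator produces gull days with known
    ground truth so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    ranger,
    lme4,
    lmerTest,
    emmeans,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
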