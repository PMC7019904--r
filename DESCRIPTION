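Package: fortiscope
Title: Fortification Scenario Modeling of Nutrient Intakes Under Updated Daily Values
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models how updating the Daily Values (DVs) on the US Nutrition
    Facts Label propagates into population nutrient intakes. Rewrites
    voluntary fortification in a source-partitioned food composition
    database so each fortified food keeps its percent-DV under the new DVs,
    merges the rewritten database with two-day 24-h dietary recalls,
    estimates usual (long-run) intake per nutrient with a Box-Cox
    mixed-effects measurement-error model, and summarizes mean usual
    intake, prevalence below the Estimated Average Requirement and at or
    above the Tolerable Upper Intake Level with survey weights and Balanced
    Repeated Replication standard errors. Includes a synthetic-data
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
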