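Package: foodgap
Title: Food Production-Consumption Gap Accounting for Oasis Metropolitan Areas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Caloric and macronutrient accounting of regional food
    self-sufficiency for nine food groups. Converts raw production mass
    into caloric and macronutrient production with edible-conversion and
    caloric factors, computes age- and sex-structured food demand under
    historical and dietary-guideline consumption structures, reports
    signed production-demand gap percentages at total-calorie,
    macronutrient, and per-food resolution, and projects future demand
    under shared socioeconomic pathway (SSP) population scenarios via
    share-based downscaling of provincial cohort projections. Includes a
    synthetic-data generator with known ground truth for validation, and
    transcriptions of the published Urumqi Metropolitan Area summary
    tables (2000-2020) as worked-example inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
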