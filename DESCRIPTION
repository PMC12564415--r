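Package: agestage
Title: Age-Stage Two-Sex Life Tables and Population Projection for Insect Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for age-stage, two-sex life table analysis of individual
    insect life-history records: age-stage survival and fecundity schedules,
    intrinsic rate of increase from the Euler-Lotka equation, net and gross
    reproductive rates, mean generation time, life-expectancy and
    reproductive-value surfaces, bootstrap inference and two-group bootstrap
    comparison of population parameters, and deterministic daily age-stage
    population projection. Includes a synthetic cohort generator that emulates
    control and larval-starvation treatments of the endangered butterfly
    Luehdorfia chinensis, calibrated to published summary statistics, so the
    full analysis runs at desk scale without the unpublished raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
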