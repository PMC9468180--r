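Package: agestage
Title: Age-Stage Two-Sex Life Table Analysis with Predation Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Age-stage, two-sex life table analysis for arthropod cohort
    studies: survival, fecundity and predation schedules from daily
    individual-level records; population parameters (net reproductive rate,
    intrinsic and finite rates of increase, mean generation time), age-stage
    life expectancy and reproductive value; predator demography (net and
    finite predation rates, transformation rate, stable age-stage
    distribution); bootstrap standard errors and paired bootstrap tests;
    deterministic population and predation projection with percentile
    confidence bands. Includes a synthetic cohort generator calibrated to a
    four-temperature Harmonia axyridis / Spodoptera litura egg-predation
    study design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
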