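Package: activehia
Title: Age-Structured Health Impact Assessment of Active Transport Scenarios
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the all-cause mortality benefits of walking and cycling
    implied by long-run national transport scenarios. Mileage trajectories are
    allocated across one-year ages by a reference age distribution, cycling is
    split between classical and electrically assisted bicycles under a
    mean-age-gap constraint, exposures are scaled through capped linear
    dose-response functions for all-cause mortality, and impacts are expressed
    as premature deaths averted, years of life lost averted, period
    life-expectancy gains, and monetized benefits with uncertainty intervals
    and sensitivity variants. A synthetic-data module generates demographic
    projections, mileage trajectories, age distributions and value-of-life-year
    series so the full pipeline runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
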