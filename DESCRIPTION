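Package: stroke90
Title: Ninety-Day Stroke Episode Costs, Mortality and Provider Profiling from Administrative Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds 90-day episodes of care for ischemic stroke (ICD-10 I63)
    from administrative claims: index-event selection, intervention
    classification (thrombectomy, thrombolysis, other), provider attribution
    with a minimum-volume filter, payer-perspective cost decomposition
    (primary hospitalization, other hospitalizations, outpatient care),
    crude and indirectly age-standardized 90-day mortality, the effective
    cost per survivor (ECPS) indicator, and Spiegelhalter funnel-plot
    control limits (exact binomial, Poisson and normal) for provider
    comparison. Ships a seeded synthetic-claims generator so the full
    pipeline is testable without access to confidential payer data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
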