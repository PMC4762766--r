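Package: idmpower
Title: Simulation-Based Power and Minimum Detectable Hazard Ratios for
    Illness-Death Cohort Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical power and minimum-detectable-hazard-ratio (MDHR)
    calculations for long-running population cohorts that follow participants
    from mid-life into old age and test environmental exposures, genetic
    exposures and their interaction against chronic-disease incidence.  The
    cohort is simulated under an irreversible illness-death model with
    age-as-time-scale left truncation (delayed entry), Weibull transition
    hazards, log-normal frailty, competing death, exponential loss to
    follow-up, panel (visit-based) disease ascertainment and non-differential
    exposure misclassification.  Each simulated dataset is analysed by
    maximum likelihood under a left-truncated Weibull proportional-hazards
    model, and power is the Monte-Carlo rejection proportion of the Wald
    test; the MDHR is found by bisection with common random numbers.  The
    closed-form Schoenfeld (1983) proportional-hazards formula is included
    as the conventional comparator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    survival,
    optparse,
    withr
Config/testthat/edition: 3
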