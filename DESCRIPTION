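Package: multistage
Title: Multistage Models of Age-Related Disease Incidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parametric multistage models for the age of onset of common
    diseases in cohorts with delayed entry. Fits Weibull proportional-hazards
    and non-sequential multistage (NSM) survival models to left-truncated,
    right-censored age-at-first-admission data by maximum likelihood; adjusts
    Kaplan-Meier curves for the cumulative hazard accrued before the first
    observed event; screens fits with chi-square goodness-of-fit tests under a
    false discovery rate correction; classifies diseases along the sporadic to
    late-onset axis from extrapolated risks at ages 50 and 100; and converts
    proportional-hazards coefficients into relative aging rates and effective
    ages. Includes a synthetic cohort generator with ICD-10 coded
    hospital-episode tables and brute-force multistage simulators used as
    test oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    survival,
    ggplot2,
    rlang,
    utils,
    yaml
Suggests:
    flexsurv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
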