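Package: edssmidpath
Title: Censoring-Bias-Adjusted Disability Progression Speed in Multiple Sclerosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating how fast neurological disability progresses
    in relapsing-onset multiple sclerosis from irregular clinic-visit records
    of the Expanded Disability Status Scale (EDSS). Detects irreversible EDSS
    endpoints in longitudinal visit tables, constructs progression paths under
    maximum, minimum and midpoint survival-time assumptions, imputes expected
    midpoint survival-time measures for interval-censored progression events
    (including equal-interval placement of endpoints skipped between
    non-adjacent observed levels), and estimates progression speed with a
    fixed-effects rate-of-change model and Kaplan-Meier survival curves.
    Includes a synthetic natural-history cohort generator with irregular
    gamma-renewal visit schedules, onset-to-first-visit gaps and transitory
    relapse elevations, so the full pipeline is testable by parameter
    recovery without access to clinical records, plus censoring-bias metrics
    (assessment rates, left/interval/right censoring windows) and a
    reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    tibble,
    jsonlite,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
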