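Package: authsieve
Title: Two-Stage Participant Authentication for Web-Based Study Enrollment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fraud and duplicate detection for fully web-based trial
    enrollment. Implements a two-stage authentication pipeline: an automated
    battery (eligibility recheck, exact/partial contact-duplicate matching
    against a registry of prior attempts, IP-geolocation consistency,
    completion-time and completion-score gates, address-cluster detection)
    followed by a checklist-driven manual review stage (survey response
    pattern screening, zip/location verification, social-media evidence,
    email verification with reminder scheduling). Ships a seeded synthetic
    cohort generator with planted, labelled anomaly archetypes for
    validating pipeline sensitivity and specificity, plus enrollment-funnel
    and status-table reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stringr,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
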