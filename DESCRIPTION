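Package: mhengage
Title: Engagement Evaluation for Mobile Health App Usage Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Evaluates user engagement with mobile-health (mHealth) apps from
    session-structured usage logs. Computes a five-subindex composite
    engagement index (click depth, loyalty, recency, feedback, interaction)
    and cumulative engagement time per participant, daily-active-user curves,
    and in-app reward ("mileage") accounting. Includes a seeded synthetic
    cohort generator that emulates the statistical structure of a 28-day
    observational mHealth study (overdispersed session counts, right-skewed
    engagement time, left-skewed engagement index), and nonparametric
    cohort comparisons (Mann-Whitney U with tie-corrected normal
    approximation, Kruskal-Wallis, Spearman rank correlation) with
    table-style reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    rlang,
    readr,
    jsonlite,
    yaml,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    ggplot2
Config/testthat/edition: 3
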