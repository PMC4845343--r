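Package: trialpub
Title: Abstract-to-Publication Concordance and Publication-Bias Analysis for
    Randomized Trial Conference Abstracts
Version: 0.1.0
Authors@R:
    person("Ivo", "Renner", email = "ivo.renner@example.org", role = c("aut", "cre"))
Description: Tools for meta-research cohorts of randomized-trial conference
    abstracts and their full publications: rule-based main-outcome selection,
    three-level statistical-significance classification, qualitative and
    quantitative discordance scoring with percent-difference banding,
    risk-ratio estimation for full publication (2x2 tables with Katz
    intervals, log-binomial regression, and an interaction model with a joint
    Wald test), Kaplan-Meier time-to-publication analysis with log-rank
    comparisons, an assumption-based imputation sensitivity analysis for
    unreported significance, and a seeded synthetic-cohort generator so the
    whole pipeline runs without access to the original extracted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
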