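Package: ppscore
Title: Psychosis Polyrisk Score Engine and Population Simulator
Version: 0.1.0
Authors@R:
    person("ppscore", "authors", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes the Psychosis Polyrisk Score (PPS), a weighted sum of
    environmental risk and protective exposures for psychosis in which each
    factor weight is expressed in points of 10*log10(odds ratio), and maps
    total scores to relative risks via RR = 10^(PPS/10). Provides the published
    scoring instrument as a validated factor registry, resolution of raw
    questionnaire responses into exposure profiles (including the combined
    immigration and ethnicity items), cohort-level summaries with quartile
    ranges and threshold proportions, a seedable Monte-Carlo simulator of the
    score distribution in a general population under configurable exposure
    prevalences with an adjusted Jarque-Bera normality test, and the
    between-group statistics used in pilot evaluations (Welch t from summary
    statistics, Fisher's exact test, one-way ANOVA with Tukey HSD, Pearson
    correlation). Includes CSV/JSON/YAML interfaces and a command-line entry
    point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
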