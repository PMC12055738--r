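Package: spizonal
Title: Zonal Disparity Analysis of Survey Health Indicators with SPI Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for zonal disparity analysis of percentage-valued survey
    health indicators, built around a Statistical Performance Index (SPI)
    style hierarchical average in which each indicator forms its own
    equally weighted dimension within a thematic pillar. Provides pillar
    scoring with an explicit missing-value denominator rule, quantile
    classification of regions (Q1 poor to Q4 excellent), zonal
    favourability scores (percentage of a zone's regions in Q3 or Q4),
    one-way and multivariate analysis of variance across zones with
    Bonferroni-adjusted pairwise post-hoc comparisons, a univariate
    regression of maternal healthcare utilisation on women empowerment,
    a seeded synthetic-data generator emulating NFHS-style factsheet
    tables, and a command-line pipeline with Markdown reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
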