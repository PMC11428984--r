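Package: apsi
Title: Agricultural Protection Against Stress Index for PGPR Strain Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds the Agricultural Protection Against Stress Index (APSI), a
    weighted 0-100 composite score that integrates a panel of plant-growth
    promotion, drought-protection, biofungicidal, nutrient-solubilization,
    siderophore, urease and phytohormone assays into a single comparable value
    per bacterial strain. Provides ingestion and validation of long-format
    assay panels, the statistical grading pipeline (Bonferroni outlier
    screening, Shapiro-Wilk normality check, one-way ANOVA, Tukey HSD with
    compact-letter display), tiered and probit raw-to-score mappings bounded
    by per-test maxima, Delphi aggregation of expert category weights with
    allocation to per-test budgets, the 50 +/- 0.5 suitability cutoff and
    competition ranking, Dirichlet weight-perturbation and bootstrap
    sensitivity analyses, and a synthetic assay-panel generator so that every
    stage is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
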