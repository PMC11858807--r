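Package: kinanthro
Title: Kinanthropometric Profiling, Somatotype Analysis and Questionnaire
    Scoring for Athlete Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cross-sectional kinanthropometry studies of athlete
    cohorts: anthropometry-derived body composition through a pluggable
    equation registry (body density from skinfolds, percent body fat, bone
    and skeletal muscle mass, technical error of measurement), Heath-Carter
    anthropometric somatotyping with somatochart coordinates, dispersion
    statistics (SDD/SDM/SAD/SAM) and the thirteen-category classification,
    scoring of the abridged sports nutrition knowledge questionnaire
    (A-NSKQ) and of the short-form international physical activity
    questionnaire (IPAQ-SF) including MET-minute conversion and activity
    categories, a group-comparison layer (Kolmogorov-Smirnov normality gate,
    two-way Type-III ANOVA or aligned-rank-transform ANOVA with partial
    eta-squared, Bonferroni pairwise post hoc, Pearson correlation with
    effect-size labels, Cochran sample-size and noncentral-F power
    utilities), and a seeded latent-factor synthetic-cohort generator for
    end-to-end pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    nortest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
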