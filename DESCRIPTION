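Package: mccat
Title: Case-Based Assessment Engine for Motivational Communication
    Competencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An assessment engine for scoring health-care-provider skill in
    motivational communication from case-based, rank-ordered multiple-choice
    tests. Provides a competency-tagged virtual-patient case bank (schema,
    validation, census, and a canonical synthetic fixture generator),
    randomized assembly of four-case assessment forms, the two-equation
    scoring algorithm (weighted per-competency subscale scores and a
    rank-based score), expert content-validation analytics (rank-agreement
    classification, consensus summaries, and modification decisions),
    reliability analytics (Cronbach's alpha over item ranks and case-variant
    consistency ANOVA), and a seeded latent-skill respondent simulator for
    end-to-end testing.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
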