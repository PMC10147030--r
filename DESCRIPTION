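Package: nupeval
Title: Multifaceted Evaluation of Neglected and Underutilized Fruit-Tree Germplasm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rubric-based evaluation pipeline for wild fruit-tree and shrub
    germplasm. Converts per-genotype measurements (rooting frequency,
    antioxidant activity, total phenolic content, juvenile tree height and
    growth rate, onset of fruit production, molecular authentication) into
    ordinal attribute scores and a per-species multifaceted-potential
    percentage; validates and aggregates 12-attribute feasibility score
    vectors into percentages with readiness-timescale classification; and
    computes the field-trial statistics feeding the rubric (per-date one-way
    ANOVA with Tukey HSD across fertilization treatments and a mixed-design
    repeated-measures decomposition), together with a seeded synthetic-trial
    generator so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
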