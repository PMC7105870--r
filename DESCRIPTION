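Package: sleepiiv
Title: Actigraphy Sleep Scoring, Night-to-Night Variability, and
    Behavior Prediction in Autism Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Minute-epoch actigraphy sleep/wake scoring with a linear
    seven-minute activity score and Webster-style rescoring, automatic
    sleep-period detection, night-level sleep measures (start, duration,
    awakenings, efficiency) with age-normative adjustment, intra-individual
    variability (mean/SD/CV) over visit-anchored one-week windows,
    mixed-effects association of caregiver-reported behavior scales with
    actigraphy statistics under Benjamini-Hochberg false-discovery control,
    and a repeated nested cross-validated elastic-net protocol with a
    goodness-of-fit-weighted feature-importance score for predicting
    anxiety. Includes a seeded synthetic-cohort generator (profiles,
    minute-level nights, wear compliance, coupled scale scores) providing
    ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    lme4,
    lmerTest,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
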