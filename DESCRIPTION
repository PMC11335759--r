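Package: stimtools
Title: Decision-Support Algorithms and Matched-Control Evaluation for
    Ovarian Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements two interpretable decision-support algorithms for
    ovarian stimulation in IVF -- a starting-dose tool that builds a
    patient-specific FSH dose-response curve by k-nearest-neighbour
    retrieval and polynomial fitting with bootstrap percentile bands, and a
    trigger-timing tool based on multi-horizon linear regressions over
    binned follicle counts and estradiol with a biological-feasibility
    constraint -- together with the matched-control evaluation pipeline used
    to assess them (KNN imputation of missing baseline covariates,
    per-physician 1-to-1 nearest-neighbour matching with replacement,
    covariate-balance diagnostics, arm comparisons, rule-based
    protocol-adherence classification, and survey-based agree/disagree
    stratification).  A seeded synthetic-cohort generator with stored
    ground truth makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
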