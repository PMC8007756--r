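Package: sleepcdm
Title: Polysomnography Results in the OMOP Common Data Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts structured polysomnography (PSG) report extracts from a
    sleep-center electronic health record into the OMOP Common Data Model
    (v5.3.1). Builds a custom standard vocabulary for 86 PSG parameters
    (concept, concept_relationship, concept_ancestor), runs a versioned
    extract-transform-load with procedure-result linkage through the
    oncology-extension modifier fields, applies declarative data-quality
    cleaning rules, and provides a patient-level prediction feasibility
    harness: target/outcome cohorts with time-at-risk, windowed covariate
    extraction with Charlson, CHA2DS2-VASc and DCSI comorbidity scores, and
    lasso / gradient-boosting / random-forest models evaluated by AUC and
    AUPRC. A seeded synthetic sleep-center EHR generator makes every stage
    testable without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    glmnet,
    ranger,
    xgboost,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
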