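Package: rwascore
Title: Automatic Quantification of REM Sleep Without Atonia from Chin EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects motor activity events in the submentalis (chin) surface
    EMG of a polysomnographic recording with an adaptive moving-window
    baseline, scores 3-second mini-epochs, and summarises REM sleep without
    atonia (RWA) as an automatic score between 0 (complete atonia) and 1
    (complete absence of atonia), together with per-stage motor-activity
    metrics. Includes a rule-based emulation of visual tonic/phasic/any RWA
    scoring, a validation-statistics layer (ROC with DeLong intervals and
    paired curve comparison, cut-point selection, correlation, one-way ANOVA
    with Bonferroni post-hoc tests, Fisher's exact test, linear regression),
    a synthetic chin-EMG and cohort generator with planted ground truth, EDF
    input/output, and a command-line interface.
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
    pROC,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
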