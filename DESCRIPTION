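Package: hypocause
Title: Inference of Hypoglycemia Causes from Type 1 Diabetes Self-Care Diaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the causes of hypoglycemia in type 1 diabetes
    from routinely collected self-care diaries. Provides a synthetic cohort
    generator for diaries of self-monitored blood glucose, insulin, carbohydrate,
    bolus-advisor and e-learning records with labelled hypoglycemia episodes; an
    83-variable event representation of each episode (temporal context,
    shape-preserving interpolated glucose curve summaries, neighbouring readings
    and intakes, bolus-advisor context, 90-day self-care statistics and quiz
    engagement); mixed-effects logistic association analysis with BIC screening,
    variance-inflation and correlation filtering; and subject-grouped nested
    cross-validated classification experiments with sequential floating forward
    feature selection, class-weighted neural network classifiers and
    F1/recall/precision/MCC reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    ranger,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
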