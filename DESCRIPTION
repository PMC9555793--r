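Package: trtcds
Title: Rule-Based Clinical Decision Support for Tinnitus Retraining Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Mines diagnostic decision rules and treatment action rules from
    visit-level clinical tables for tinnitus retraining therapy (TRT),
    translates mined rules into an explainable knowledge base, and runs
    confidence-ranked forward-chaining inference to support diagnosis
    (patient category C0-C4) and treatment recommendation. Includes a
    synthetic longitudinal cohort generator with plantable diagnostic
    signatures and treatment effects, Tinnitus Handicap Inventory scoring
    and change metrics, chi-square feature ranking, a categorical Naive
    Bayes baseline, and an evaluation harness for accuracy, coverage and
    explanation faithfulness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
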