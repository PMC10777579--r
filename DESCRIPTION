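Package: refdx
Title: Hybrid Attention-CNN Classification of GP Referral Letters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for primary-diagnosis triage of free-text GP referral
    letters over four neurological ICD classes (G40, R51, M54, I63).
    Implements a four-step preprocessing pipeline (cleaning, negation-aware
    symptom extraction, symptom dot separating, complaint-symptoms
    integration), a synthetic referral-letter generator for end-to-end
    testing, word-level and subword text encodings, and a hybrid two-branch
    classifier that couples a small transformer encoder with a 1-D
    convolutional net through an adaptively weighted joint loss. Includes a
    stratified experiment protocol, accuracy evaluation over a grid of
    architectures and dataset variants, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
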