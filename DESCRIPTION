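Package: pdfuzz
Title: Fuzzy Neural Network Risk Prediction for Parkinson's Disease Voice Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-stage pipeline for predicting Parkinson's disease from
    tabular dysphonia (voice) features: z-score plus min-max preprocessing
    with missing-value handling and outlier removal, a two-class
    disease-affect scaling rate (DASR) feature weighting, a logistic-decision
    entropy/information-gain feature selection (LDEFS) with
    mutual-information ordering, and a trainable four-layer fuzzy neural
    network classifier with Gaussian fuzzification, linear rule consequents,
    a softmax class head, momentum gradient training, and low/medium/high
    risk stratification. Includes a synthetic voice-feature data generator
    with planted informative features so every stage is testable without
    external downloads, plus a confusion-matrix evaluation harness and
    model-comparison utilities.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
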