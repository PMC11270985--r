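Package: multistress
Title: Multi-Stressor Toxicity Prediction with Null Models and the Stress Addition Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the combined effects of chemical and
    environmental stressors on aquatic invertebrates. Fits five-parameter
    log-logistic dose-response curves to binomial immobility data, computes
    ECx values with delta-method confidence intervals, predicts mixture and
    multiple-stressor EC50s under concentration addition, effect addition
    (independent action) and the stress addition model (SAM), quantifies
    synergism by model deviation ratios, converts measured environmental
    concentrations to toxic units, and simulates full-factorial acute
    toxicity experiments with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    generics
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
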