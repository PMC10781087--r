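Package: traitmap
Title: Bottom-Up Construction of Brief Personality Scales That Predict Body Mass
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for describing and predicting a continuous health outcome
    (body mass index) from large pools of questionnaire items collected under
    planned missingness, as in Synthetic Aperture Personality Assessment (SAPA)
    designs. Implements dual-dataset item screening on covariate-residualized
    item-outcome correlations, exploratory factor analysis with parallel
    analysis and direct oblimin rotation, cross-sample factor replication
    checks (Tucker congruence, squared loading differences), greedy item
    winnowing into brief predictive scales, elastic-net out-of-sample
    prediction, and decile risk stratification. Ships a synthetic SAPA-style
    data generator with known ground truth so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
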