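Package: weightcast
Title: Piecewise-Linear Mixture Modelling of Body-Weight Trajectories from Health-Checkup Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for predicting adult body weight over a three-year horizon from
    annual health-checkup records. Ships the published five-formula piecewise-linear
    predictor (a BMI/age/sex-gated tree of sparse linear models over lifestyle
    questionnaire features) as an executable, serialisable artifact; a synthetic
    longitudinal cohort generator calibrated to the published cohort characteristics;
    a heterogeneous-mixture learner (greedy penalised-likelihood gating-tree search
    with forward-selected sparse linear leaves) able to re-discover the published
    structure from data; chained multi-year forecasting with lifestyle-scenario
    comparison; and an evaluation layer (RMSE, multiple-regression baseline,
    cohort-comparison statistics, parameter-recovery diagnostics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
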