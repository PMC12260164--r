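Package: txlearner
Title: Transformer-Based X-Learner for Drug Treatment Effects from
    Longitudinal Health Records
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates individual and average treatment effects of drug
    exposures on a 180-day binary infection outcome from longitudinal
    dispensing and admission code sequences. A transformer encoder over
    time-stamped BNF/ICD-10 code streams, fused with static covariates
    (age, sex, deprivation decile, diabetes), serves as the base risk
    model inside an X-learner meta-algorithm that imputes counterfactual
    outcomes, regresses imputed effects, and combines the effect surfaces
    with propensity weights. Includes a synthetic-cohort simulator with
    known ground-truth propensities and treatment effects, study-style
    cohort construction (eligibility, BNF-prefix exposure, composite
    outcome, wave splitting, stratified undersampling), comparison
    baselines (logistic regression, gradient-boosted trees, LSTM),
    cross-validated evaluation with precision-recall metrics, paired
    signed-rank effect-size analyses, and parameter-recovery diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    xgboost,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'cohort.R'
    'encode.R'
    'evaluation.R'
    'pipeline.R'
    'risk_models.R'
    'simulate.R'
    'txlearner-package.R'
    'utils.R'
    'xlearner.R'
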