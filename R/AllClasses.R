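setClassUnion("functionOrNULL", c("function", "NULL"))

#' Analysis wave definition
#'
#' A pandemic wave is defined by a lookback window, over which exposures and
#' input code sequences are assembled, and a follow-up window of
#' `followupDays` days starting at `followupStart`, over which the composite
#' outcome is assessed. Windows are half-open `[start, end)` at day
#' resolution, and the lookback window ends exactly where follow-up starts.
#'
#' @slot waveId integer wave identifier (1 or 2).
#' @slot lookbackStart,lookbackEnd `Date`; the exposure/feature window.
#' @slot followupStart `Date`; equals `lookbackEnd`.
#' @slot followupDays integer length of the outcome window in days.
#' @export
setClass("WaveDefinition",
  representation(
    waveId = "integer",
    lookbackStart = "Date",
    lookbackEnd = "Date",
    followupStart = "Date",
    followupDays = "integer"
  )
)

setValidity("WaveDefinition", function(object) {
  msg <- character()
  if (object@lookbackEnd <= object@lookbackStart)
    msg <- c(msg, "lookbackEnd must be after lookbackStart")
  if (object@lookbackEnd != object@followupStart)
    msg <- c(msg, "lookbackEnd must equal followupStart")
  if (object@followupDays <= 0L)
    msg <- c(msg, "followupDays must be positive")
  if (length(msg)) msg else TRUE
})

#' Drug class defined by BNF code prefixes
#'
#' A study medication class is identified by one or more British National
#' Formulary (BNF) code prefixes; any dispensing record whose code starts
#' with one of the prefixes counts as exposure to the class.
#'
#' @slot name character class name (e.g. "ACEI").
#' @slot bnfPrefixes character vector of BNF code prefixes.
#' @export
setClass("DrugClass",
  representation(name = "character", bnfPrefixes = "character")
)

setValidity("DrugClass", function(object) {
  if (length(object@bnfPrefixes) == 0L || any(!nzchar(object@bnfPrefixes)))
    "bnfPrefixes must be a non-empty vector of non-empty strings"
  else TRUE
})

#' Configuration of the synthetic cohort simulator
#'
#' Captures everything the simulator needs to generate a cohort with known
#' ground truth: cohort size and seed, wave structure, background event
#' rates and code vocabulary, confounded treatment assignment, per-drug
#' treatment effects on the risk-difference scale, and the outcome model.
#'
#' @slot nPatients positive integer number of patients.
#' @slot seed integer master seed; per-patient streams are derived from it.
#' @slot waveCount integer, 1 or 2 pandemic waves.
#' @slot followupDays integer outcome window length (days).
#' @slot baseEventRate numeric mean number of background code events per
#'   patient per lookback window.
#' @slot vocabSpec data.frame with columns `code`, `code_system`, `freq`
#'   giving the background code vocabulary and relative frequencies.
#' @slot confoundingStrength numeric >= 0 scaling of the covariate effects
#'   in the treatment-assignment (propensity) model.
#' @slot treatmentEffects named list, one element per simulated drug class;
#'   each is a constant risk difference or a `function(demographics)`
#'   returning one risk difference per patient.
#' @slot outcomeBasePrevalence numeric in (0,1); target outcome prevalence
#'   under no treatment effect.
#' @slot waveShare numeric in (0,1); fraction of total incidence falling in
#'   wave 1 (only used when `waveCount == 2`).
#' @slot treatmentPrevalence named numeric; target marginal exposure
#'   prevalence per drug.
#' @slot riskCoefs named numeric additive risk-difference coefficients of
#'   the baseline outcome model (age_per_year, male, simd_per_decile,
#'   diabetes, comorbidity).
#' @slot propensityCoefs named numeric log-odds coefficients of the
#'   treatment-assignment model (same names; comorbidity acts on
#'   `log1p(count)`).
#' @slot clipTolerance numeric; configs whose pre-clipping outcome
#'   probabilities leave `[0, 1]` by more than this are rejected.
#' @export
setClass("SimulationConfig",
  representation(
    nPatients = "integer",
    seed = "integer",
    waveCount = "integer",
    followupDays = "integer",
    baseEventRate = "numeric",
    vocabSpec = "data.frame",
    confoundingStrength = "numeric",
    treatmentEffects = "list",
    outcomeBasePrevalence = "numeric",
    waveShare = "numeric",
    treatmentPrevalence = "numeric",
    riskCoefs = "numeric",
    propensityCoefs = "numeric",
    clipTolerance = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nPatients < 1L) msg <- c(msg, "nPatients must be positive")
  if (!object@waveCount %in% c(1L, 2L))
    msg <- c(msg, "waveCount must be 1 or 2")
  if (object@outcomeBasePrevalence <= 0 || object@outcomeBasePrevalence >= 1)
    msg <- c(msg, "outcomeBasePrevalence must lie in (0, 1)")
  if (object@waveShare <= 0 || object@waveShare >= 1)
    msg <- c(msg, "waveShare must lie in (0, 1)")
  if (object@confoundingStrength < 0)
    msg <- c(msg, "confoundingStrength must be >= 0")
  if (object@followupDays <= 0L) msg <- c(msg, "followupDays must be > 0")
  if (!all(c("code", "code_system", "freq") %in% names(object@vocabSpec)))
    msg <- c(msg, "vocabSpec needs columns code, code_system, freq")
  if (length(object@treatmentEffects) &&
      is.null(names(object@treatmentEffects)))
    msg <- c(msg, "treatmentEffects must be a named list")
  if (!all(names(object@treatmentEffects) %in%
           names(object@treatmentPrevalence)))
    msg <- c(msg, "every treated drug needs a treatmentPrevalence entry")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort with ground truth
#'
#' Container returned by [simulateCohort()]: the three raw tables consumed
#' by the cohort builder (events, demographics, outcomes) plus the
#' simulator-only ground truth (true propensity, true individual treatment
#' effect and true arm-specific outcome probabilities per patient and drug).
#'
#' @slot demographics data.frame (patient_id, age, sex, simd_decile,
#'   diabetes).
#' @slot events data.frame (patient_id, event_date, code, code_system),
#'   sorted by (patient_id, event_date, code_system, code).
#' @slot outcomes data.frame (patient_id, test_date, hosp_date, death_date).
#' @slot groundTruth data.frame (patient_id, drug, true_propensity,
#'   true_ite, true_outcome_prob_treated, true_outcome_prob_control,
#'   exposed).
#' @slot config the [SimulationConfig-class] used.
#' @export
setClass("SyntheticCohort",
  representation(
    demographics = "data.frame",
    events = "data.frame",
    outcomes = "data.frame",
    groundTruth = "data.frame",
    config = "SimulationConfig"
  )
)

#' Labeled analysis cohort
#'
#' Output of [buildCohort()]: per-patient wave assignment, per-drug exposure
#' indicators, the binary 180-day outcome and event day, together with the
#' exclusion log and the undersampling ratio actually applied.
#'
#' @slot labels data.frame with patient_id, wave_id, Y, event_day and one
#'   exposure column per drug class.
#' @slot exclusions data.frame (reason, n) exclusion log.
#' @slot undersamplingRatio numeric keep-fraction applied to wave-1
#'   negatives (NA when a single wave is analysed).
#' @slot waves list of [WaveDefinition-class].
#' @slot drugs list of [DrugClass-class].
#' @export
setClass("LabeledCohort",
  representation(
    labels = "data.frame",
    exclusions = "data.frame",
    undersamplingRatio = "numeric",
    waves = "list",
    drugs = "list"
  )
)

#' Token vocabulary over medical codes
#'
#' Maps truncated BNF/ICD-10 codes to integer token ids. Ids 0, 1 and 2 are
#' reserved for PAD, UNK and CLS; real tokens are numbered from 3 in order
#' of descending training-corpus count (ties broken lexicographically), so
#' two builds on the same corpus give identical ids. Built from training
#' folds only.
#'
#' @slot tokens data.frame (token, id, count, code_system).
#' @slot reserved named integer vector (PAD = 0, UNK = 1, CLS = 2).
#' @slot bnfChars,icdChars integer truncation lengths for BNF and ICD-10
#'   codes.
#' @slot minCount integer; codes rarer than this map to UNK.
#' @export
setClass("CodeVocabulary",
  representation(
    tokens = "data.frame",
    reserved = "integer",
    bnfChars = "integer",
    icdChars = "integer",
    minCount = "integer"
  )
)

setValidity("CodeVocabulary", function(object) {
  msg <- character()
  tk <- object@tokens
  if (nrow(tk)) {
    if (anyDuplicated(tk$token)) msg <- c(msg, "duplicate tokens")
    if (anyDuplicated(tk$id)) msg <- c(msg, "duplicate token ids")
    if (any(tk$id < 3L)) msg <- c(msg, "real token ids must start at 3")
  }
  if (!identical(unname(object@reserved), 0:2))
    msg <- c(msg, "reserved ids must be PAD=0, UNK=1, CLS=2")
  if (length(msg)) msg else TRUE
})

#' Encoded patient batch
#'
#' Model-ready representation of a patient batch: right-padded token id and
#' day-offset matrices, a padding mask, and the static covariate matrix
#' (standardised age, male indicator, SIMD decile, diabetes flag). Events
#' retained per patient are the `maxLen` most recent lookback events.
#'
#' @slot patientId character vector, one per row.
#' @slot tokenIds integer matrix n x maxLen (0 = PAD).
#' @slot dayOffsets integer matrix n x maxLen, days since lookback start
#'   (0 at PAD positions); non-decreasing over real tokens.
#' @slot paddingMask logical matrix n x maxLen, TRUE at PAD positions.
#' @slot staticFeatures numeric matrix n x 4 (age_z, male, simd, diabetes).
#' @slot maxLen integer sequence capacity.
#' @slot lookbackDays integer length of the lookback window in days.
#' @slot vocab the [CodeVocabulary-class] used for encoding.
#' @slot scaler list with `ageMean`, `ageSd` used for age standardisation.
#' @export
setClass("EncodedCohort",
  representation(
    patientId = "character",
    tokenIds = "matrix",
    dayOffsets = "matrix",
    paddingMask = "matrix",
    staticFeatures = "matrix",
    maxLen = "integer",
    lookbackDays = "integer",
    vocab = "CodeVocabulary",
    scaler = "list"
  )
)

setValidity("EncodedCohort", function(object) {
  msg <- character()
  d <- dim(object@tokenIds)
  if (!identical(d, dim(object@dayOffsets)) ||
      !identical(d, dim(object@paddingMask)))
    msg <- c(msg, "tokenIds, dayOffsets and paddingMask must share dims")
  if (d[1] != length(object@patientId))
    msg <- c(msg, "one patientId per row required")
  if (d[1] != nrow(object@staticFeatures))
    msg <- c(msg, "one static feature row per patient required")
  if (d[2] != object@maxLen) msg <- c(msg, "ncol must equal maxLen")
  if (length(msg)) msg else TRUE
})

#' Virtual parent of all fitted outcome-risk models
#'
#' All risk models share the contract: `predictRisk(model, encoded)` returns
#' finite probabilities in `[0, 1]`, one per patient, deterministically for
#' a fixed seed.
#' @export
setClass("RiskModel", representation("VIRTUAL"))

#' Transformer hyperparameter set
#'
#' @slot embedDim token embedding width; must be divisible by `nHeads`.
#' @slot nHeads number of self-attention heads.
#' @slot nLayers number of encoder layers.
#' @slot ffDim width of the position-wise feed-forward sublayer.
#' @slot headDim width of the hidden layer of the classification head.
#' @slot dropout dropout rate applied after attention, after the
#'   feed-forward sublayer and in the head.
#' @slot maxLen maximum number of events retained per patient.
#' @slot learningRate,batchSize,epochs,patience,valFraction Adam training
#'   schedule with early stopping on a stratified validation split.
#' @slot timeBucketDays width (days) of the learned time-embedding buckets.
#' @slot seed integer controlling initialisation, shuffling and dropout.
#' @export
setClass("TransformerConfig",
  representation(
    embedDim = "integer", nHeads = "integer", nLayers = "integer",
    ffDim = "integer", headDim = "integer", dropout = "numeric",
    maxLen = "integer", learningRate = "numeric", batchSize = "integer",
    epochs = "integer", patience = "integer", valFraction = "numeric",
    timeBucketDays = "integer", seed = "integer"
  )
)

setValidity("TransformerConfig", function(object) {
  msg <- character()
  if (object@embedDim %% object@nHeads != 0L)
    msg <- c(msg, "embedDim must be divisible by nHeads")
  pos <- c(object@embedDim, object@nHeads, object@nLayers, object@ffDim,
           object@headDim, object@maxLen, object@batchSize, object@epochs,
           object@timeBucketDays)
  if (any(pos <= 0L)) msg <- c(msg, "all dimensions must be positive")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must lie in [0, 1)")
  if (object@valFraction <= 0 || object@valFraction >= 0.5)
    msg <- c(msg, "valFraction must lie in (0, 0.5)")
  if (length(msg)) msg else TRUE
})

#' Fitted transformer risk model
#'
#' @slot weights named list of parameter matrices (embeddings, per-layer
#'   attention/feed-forward/layer-norm weights, classification head).
#' @slot config the [TransformerConfig-class] used.
#' @slot log data.frame training log (epoch, train_loss, val_loss).
#' @slot vocabSize integer number of embedding rows (reserved + real).
#' @slot nBuckets integer number of time buckets.
#' @slot staticDim integer number of static features.
#' @export
setClass("TransformerModel", contains = "RiskModel",
  representation(
    weights = "list", config = "TransformerConfig", log = "data.frame",
    vocabSize = "integer", nBuckets = "integer", staticDim = "integer"
  )
)

#' Fitted LSTM baseline
#'
#' @slot weights named list of parameter matrices.
#' @slot config named list of hyperparameters.
#' @slot log data.frame training log.
#' @slot vocabSize,nBuckets,staticDim integer dimensions.
#' @export
setClass("LSTMModel", contains = "RiskModel",
  representation(
    weights = "list", config = "list", log = "data.frame",
    vocabSize = "integer", nBuckets = "integer", staticDim = "integer"
  )
)

#' Fitted logistic-regression baseline
#'
#' Operates on bag-of-token counts plus static features.
#'
#' @slot coef named numeric coefficient vector (incl. intercept).
#' @slot featureNames character feature order used at fit time.
#' @export
setClass("LogisticRiskModel", contains = "RiskModel",
  representation(coef = "numeric", featureNames = "character")
)

#' Fitted gradient-boosted-trees baseline
#'
#' Wraps an xgboost booster over bag-of-token counts plus static features.
#'
#' @slot booster the fitted `xgb.Booster`.
#' @slot featureNames character feature order used at fit time.
#' @export
setClass("BoostedTreesModel", contains = "RiskModel",
  representation(booster = "ANY", featureNames = "character")
)

#' Risk model defined by an arbitrary prediction function
#'
#' Used to inject hand-specified outcome surfaces (e.g. frozen oracle
#' functions in algebra checks). The function receives an
#' [EncodedCohort-class] and returns one probability per patient.
#'
#' @slot fn the prediction function.
#' @export
setClass("FunctionRiskModel", contains = "RiskModel",
  representation(fn = "function")
)

#' Fitted X-learner for one drug class
#'
#' Holds the five sub-models of the X-learner (outcome surfaces mu0/mu1,
#' imputed-effect regressors tau0/tau1, propensity g) together with the
#' encoding context (vocabulary, static scaler, leakage-guard prefixes)
#' needed to score new patients.
#'
#' @slot drug the [DrugClass-class] analysed.
#' @slot mu0,mu1 fitted [RiskModel-class] outcome surfaces (controls /
#'   treated).
#' @slot tau0Fn,tau1Fn functions mapping the stage-3 feature matrix to
#'   imputed-effect predictions.
#' @slot gFn function mapping the stage-3 feature matrix to propensity
#'   scores (already clipped).
#' @slot epsilon numeric propensity clipping bound.
#' @slot vocab the [CodeVocabulary-class] of the outcome surfaces.
#' @slot scaler list age-standardisation statistics.
#' @slot wave the [WaveDefinition-class] analysed.
#' @slot maxLen integer sequence capacity used.
#' @slot imputed data.frame of stage-2 imputed effects (patient_id, arm, D).
#' @slot seed integer.
#' @export
setClass("XLearnerFit",
  representation(
    drug = "DrugClass",
    mu0 = "RiskModel", mu1 = "RiskModel",
    tau0Fn = "function", tau1Fn = "function", gFn = "function",
    epsilon = "numeric",
    vocab = "CodeVocabulary", scaler = "list",
    wave = "WaveDefinition", maxLen = "integer",
    imputed = "data.frame", seed = "integer"
  )
)
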