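#' @include AllClasses.R
NULL

#' Predict outcome risk for encoded patients
#'
#' Applies a fitted risk model to a batch of encoded patients and returns
#' per-patient probabilities of the 180-day outcome, order-aligned with the
#' input.
#'
#' @param object a fitted risk model (e.g. [TransformerModel-class],
#'   [LogisticRiskModel-class], [BoostedTreesModel-class],
#'   [LSTMModel-class]).
#' @param encoded an [EncodedCohort-class] produced with the same vocabulary
#'   the model was trained on.
#' @param ... further arguments for methods.
#' @return numeric vector of probabilities in `[0, 1]`, one per patient.
#' @export
setGeneric("predictRisk", function(object, encoded, ...)
  standardGeneric("predictRisk"))

#' @rdname accessors
#' @export
setGeneric("cohortEvents", function(object) standardGeneric("cohortEvents"))

#' @rdname accessors
#' @export
setGeneric("cohortDemographics", function(object)
  standardGeneric("cohortDemographics"))

#' @rdname accessors
#' @export
setGeneric("cohortOutcomes", function(object)
  standardGeneric("cohortOutcomes"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("cohortLabels", function(object) standardGeneric("cohortLabels"))

#' @rdname accessors
#' @export
setGeneric("exclusionLog", function(object) standardGeneric("exclusionLog"))

#' @rdname accessors
#' @export
setGeneric("vocabTokens", function(object) standardGeneric("vocabTokens"))

#' @rdname accessors
#' @export
setGeneric("vocabSize", function(object) standardGeneric("vocabSize"))

#' @rdname accessors
#' @export
setGeneric("tokenIds", function(object) standardGeneric("tokenIds"))

#' @rdname accessors
#' @export
setGeneric("dayOffsets", function(object) standardGeneric("dayOffsets"))

#' @rdname accessors
#' @export
setGeneric("paddingMask", function(object) standardGeneric("paddingMask"))

#' @rdname accessors
#' @export
setGeneric("staticFeatures", function(object)
  standardGeneric("staticFeatures"))

#' @rdname accessors
#' @export
setGeneric("patientIds", function(object) standardGeneric("patientIds"))

#' @rdname accessors
#' @export
setGeneric("trainingLog", function(object) standardGeneric("trainingLog"))
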