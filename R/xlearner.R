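# X-learner meta-algorithm around any risk model.
#
# Stage 1 fits outcome surfaces mu0/mu1 on the control/treated arms.
# Stage 2 imputes per-patient effects from counterfactual predictions:
# D1_i = Y_i - mu0(x_i) for treated i, D0_j = mu1(x_j) - Y_j for controls.
# Stage 3 regresses D1/D0 on covariate summaries to obtain effect surfaces
# tau1/tau0 and combines them with a propensity score g(x):
# tau_hat(x) = g(x) tau0(x) + (1 - g(x)) tau1(x).

# Row-subset of an EncodedCohort.
encodedSubset <- function(encoded, idx) {
  methods::new("EncodedCohort",
    patientId = encoded@patientId[idx],
    tokenIds = encoded@tokenIds[idx, , drop = FALSE],
    dayOffsets = encoded@dayOffsets[idx, , drop = FALSE],
    paddingMask = encoded@paddingMask[idx, , drop = FALSE],
    staticFeatures = encoded@staticFeatures[idx, , drop = FALSE],
    maxLen = encoded@maxLen, lookbackDays = encoded@lookbackDays,
    vocab = encoded@vocab, scaler = encoded@scaler)
}

#' Default stage-3 effect-surface learner (gradient-boosted trees)
#'
#' Returns a factory fitting a boosted-tree regression of imputed effects
#' on the stage-3 features. The imputed effects D carry Bernoulli-scale
#' noise much larger than the effect signal, so the defaults are strongly
#' regularised (shallow trees, small learning rate and, unless overridden,
#' a minimum child weight of 2% of the training rows, at least 20); this
#' keeps the fitted effect surface smooth instead of chasing imputation
#' noise.
#'
#' @param nrounds,eta,maxDepth xgboost parameters.
#' @param minChildWeight minimum child weight; `NULL` (default) adapts it
#'   to `max(20, 0.10 * nrow(X))`.
#' @return function(X, d, seed) returning a prediction function.
#' @export
boostedEffectLearner <- function(nrounds = 200L, eta = 0.05,
                                 maxDepth = 2L, minChildWeight = NULL) {
  force(nrounds); force(eta); force(maxDepth); force(minChildWeight)
  function(X, d, seed) {
    mcw <- minChildWeight %||% max(20, ceiling(0.10 * nrow(X)))
    bst <- xgboost::xgb.train(
      params = list(objective = "reg:squarederror", eta = eta,
                    max_depth = maxDepth,
                    min_child_weight = mcw,
                    nthread = 1L, seed = seed),
      data = xgboost::xgb.DMatrix(X, label = d),
      nrounds = nrounds, verbose = 0)
    function(Xnew) as.numeric(stats::predict(bst,
                                             xgboost::xgb.DMatrix(Xnew)))
  }
}

#' Default propensity learner (logistic regression)
#'
#' Logistic regression of the treatment indicator on static features plus
#' log1p token counts per code system.
#'
#' @return function(X, t, seed) returning a prediction function.
#' @export
logisticPropensityLearner <- function() {
  function(X, t, seed) {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, X), t, family = stats::binomial()))
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    function(Xnew) as.numeric(stats::plogis(cbind(1, Xnew) %*% cf))
  }
}

resolveBaseLearner <- function(baseLearner, baseConfig) {
  if (is.function(baseLearner)) return(baseLearner)
  kind <- match.arg(baseLearner,
                    c("transformer", "logistic", "boosted_trees", "lstm"))
  if (kind == "transformer") {
    function(encoded, y, seed) {
      cfg <- if (methods::is(baseConfig, "TransformerConfig")) baseConfig
             else transformerConfig()
      cfg@seed <- as.integer(seed)
      trainTransformer(encoded, y, cfg)
    }
  } else {
    function(encoded, y, seed) {
      cfg <- if (is.list(baseConfig)) baseConfig else list()
      cfg$seed <- as.integer(seed)
      trainBaseline(encoded, y, kind, cfg)
    }
  }
}

#' Fit the X-learner for one drug class
#'
#' Runs the three X-learner stages on one wave's labelled cohort. The
#' target drug's own dispensing codes are removed from every encoded input
#' (leakage guard), so the treatment indicator cannot be read off the
#' sequence. All sub-fits are seeded deterministically from `seed`.
#'
#' @param cohort a [LabeledCohort-class] (or its labels data.frame with an
#'   `attr`-free structure; then `wave` must be given).
#' @param drug a [DrugClass-class] or the name of a default class.
#' @param events,demographics raw tables covering the cohort patients.
#' @param waveId which wave of the cohort to analyse (default: first
#'   present).
#' @param baseLearner `"transformer"` (default), `"logistic"`,
#'   `"boosted_trees"`, `"lstm"`, or a factory
#'   `function(encoded, y, seed)` returning a [RiskModel-class].
#' @param baseConfig config passed to the base learner (a
#'   [TransformerConfig-class] or a named list for the baselines).
#' @param effectLearner factory `function(X, d, seed)` for the stage-3
#'   effect surfaces; default [boostedEffectLearner()].
#' @param propensityLearner factory `function(X, t, seed)` for g(x);
#'   default [logisticPropensityLearner()].
#' @param maxLen sequence capacity for encoding.
#' @param epsilon propensity clipping bound (default 0.01).
#' @param minArmSize smallest allowed arm (default 50; abort below).
#' @param vocabMinCount vocabulary minimum token count.
#' @param ensembleSize number of independently seeded base-learner fits
#'   averaged for each outcome surface (default 1). Small seed ensembles
#'   reduce the run-to-run variance that stochastic training injects into
#'   the imputed effects.
#' @param seed master seed for all sub-fits.
#' @return an [XLearnerFit-class].
#' @export
fitXLearner <- function(cohort, drug, events, demographics,
                        waveId = NULL,
                        baseLearner = "transformer",
                        baseConfig = NULL,
                        effectLearner = boostedEffectLearner(),
                        propensityLearner = logisticPropensityLearner(),
                        maxLen = 256L, epsilon = 0.01, minArmSize = 50L,
                        vocabMinCount = 1L, ensembleSize = 1L,
                        seed = 1L) {
  if (is.character(drug)) drug <- defaultDrugClasses()[[drug]]
  stopifnot(methods::is(drug, "DrugClass"))
  labels <- cohortLabels(cohort)
  if (is.null(waveId)) waveId <- min(labels$wave_id)
  wave <- Filter(function(w) w@waveId == waveId, cohort@waves)[[1]]
  labels <- labels[labels$wave_id == waveId, , drop = FALSE]
  if (!drug@name %in% names(labels))
    stop("cohort has no exposure column for drug ", drug@name)
  tr <- labels[[drug@name]] == 1L
  y <- labels$Y
  if (sum(tr) < minArmSize || sum(!tr) < minArmSize)
    stop(sprintf("arm too small for %s: treated %d, control %d (min %d)",
                 drug@name, sum(tr), sum(!tr), minArmSize))
  if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L)
    stop("single-class outcome within an arm; cannot fit outcome surfaces")

  excl <- drug@bnfPrefixes
  evWin <- events[events$patient_id %in% labels$patient_id &
                    as.Date(events$event_date) >= wave@lookbackStart &
                    as.Date(events$event_date) < wave@lookbackEnd, ,
                  drop = FALSE]
  evWin <- evWin[!startsWithAny(evWin$code, excl), , drop = FALSE]
  vocab <- buildVocabulary(evWin, minCount = vocabMinCount)
  scaler <- staticScaler(
    demographics[demographics$patient_id %in% labels$patient_id, ,
                 drop = FALSE])
  enc <- encodePatients(labels$patient_id, events, demographics, wave,
                        vocab, maxLen = maxLen, excludePrefixes = excl,
                        scaler = scaler)

  baseFactory <- resolveBaseLearner(baseLearner, baseConfig)
  if (ensembleSize > 1L) {
    single <- baseFactory
    baseFactory <- function(encoded, y, seed) {
      fits <- lapply(seq_len(ensembleSize), function(k)
        single(encoded, y, deriveSeed(seed, k, 13L)))
      functionRiskModel(function(e)
        rowMeans(vapply(fits, function(f) predictRisk(f, e),
                        numeric(nrow(e@tokenIds)))))
    }
  }
  enc1 <- encodedSubset(enc, which(tr))
  enc0 <- encodedSubset(enc, which(!tr))
  mu1 <- baseFactory(enc1, y[tr], deriveSeed(seed, 1L, 11L))
  mu0 <- baseFactory(enc0, y[!tr], deriveSeed(seed, 2L, 11L))

  d1 <- pmin(1, pmax(-1, y[tr] - predictRisk(mu0, enc1)))
  d0 <- pmin(1, pmax(-1, predictRisk(mu1, enc0) - y[!tr]))

  feats <- featureMatrix(enc, "systems")
  tau1Fn <- effectLearner(feats[tr, , drop = FALSE], d1,
                          deriveSeed(seed, 3L, 11L))
  tau0Fn <- effectLearner(feats[!tr, , drop = FALSE], d0,
                          deriveSeed(seed, 4L, 11L))
  gRaw <- propensityLearner(feats, as.numeric(tr),
                            deriveSeed(seed, 5L, 11L))
  eps <- epsilon
  gFn <- function(Xnew) pmin(1 - eps, pmax(eps, gRaw(Xnew)))

  imputed <- rbind(
    data.frame(patient_id = enc1@patientId, arm = "treated", D = d1,
               stringsAsFactors = FALSE),
    data.frame(patient_id = enc0@patientId, arm = "control", D = d0,
               stringsAsFactors = FALSE))

  methods::new("XLearnerFit", drug = drug, mu0 = mu0, mu1 = mu1,
               tau0Fn = tau0Fn, tau1Fn = tau1Fn, gFn = gFn,
               epsilon = epsilon, vocab = vocab, scaler = scaler,
               wave = wave, maxLen = as.integer(maxLen),
               imputed = imputed, seed = as.integer(seed))
}

#' Estimate individual treatment effects
#'
#' Scores patients with the fitted X-learner:
#' `tau_hat(x) = g(x) tau0(x) + (1 - g(x)) tau1(x)`, clipped to `[-1, 1]`.
#'
#' @param fit an [XLearnerFit-class].
#' @param patientIds patients to score.
#' @param events,demographics raw tables covering those patients.
#' @return data.frame (patient_id, drug, tau_hat, g, tau0, tau1) with the
#'   distribution summary (median, IQR) in `attr(, "summary")`.
#' @export
estimateIte <- function(fit, patientIds, events, demographics) {
  enc <- encodePatients(patientIds, events, demographics, fit@wave,
                        fit@vocab, maxLen = fit@maxLen,
                        excludePrefixes = fit@drug@bnfPrefixes,
                        scaler = fit@scaler)
  feats <- featureMatrix(enc, "systems")
  g <- fit@gFn(feats)
  t0 <- fit@tau0Fn(feats)
  t1 <- fit@tau1Fn(feats)
  tau <- pmin(1, pmax(-1, g * t0 + (1 - g) * t1))
  out <- data.frame(patient_id = as.character(patientIds),
                    drug = fit@drug@name, tau_hat = tau, g = g,
                    tau0 = t0, tau1 = t1, stringsAsFactors = FALSE)
  q <- stats::quantile(tau, c(0.25, 0.5, 0.75), names = FALSE)
  attr(out, "summary") <- data.frame(drug = fit@drug@name, n = length(tau),
                                     median = q[2], iqr_low = q[1],
                                     iqr_high = q[3])
  out
}

#' Aggregate individual effects into an average treatment effect
#'
#' The ATE is the mean of `tau_hat` over the evaluation population; the
#' propensity weighting already lives inside `tau_hat`, so `"uniform"` and
#' `"propensity_combination"` coincide by construction. Dispersion is
#' reported as the SD of the `tau_hat` distribution, plus median and IQR.
#'
#' @param iteResult output of [estimateIte()].
#' @param weighting weighting scheme (see above).
#' @return one-row data.frame (drug, ate, sd, median, iqr_low, iqr_high, n).
#' @export
estimateAte <- function(iteResult,
                        weighting = c("uniform", "propensity_combination")) {
  weighting <- match.arg(weighting)
  if (nrow(iteResult) == 0L) stop("empty population: no ITEs to average")
  tau <- iteResult$tau_hat
  q <- stats::quantile(tau, c(0.25, 0.5, 0.75), names = FALSE)
  data.frame(drug = iteResult$drug[1], ate = mean(tau),
             sd = stats::sd(tau), median = q[2], iqr_low = q[1],
             iqr_high = q[3], n = length(tau), stringsAsFactors = FALSE)
}

setMethod("show", "XLearnerFit", function(object) {
  cat("XLearnerFit:", object@drug@name, "(",
      sum(object@imputed$arm == "treated"), "treated /",
      sum(object@imputed$arm == "control"), "controls ), base model:",
      class(object@mu1), "\n")
})
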