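# Synthetic cohort simulator.
#
# Generates patients whose statistical structure mirrors the study data
# model: static covariates (age >= 40, sex, SIMD decile, diabetes), sparse
# time-stamped BNF/ICD-10 event streams over the wave lookback windows,
# confounded drug exposure materialised as dispensing events, and a rare
# composite outcome drawn additively on the risk-difference scale. Ground
# truth (true propensity, true ITE, arm-specific outcome probabilities) is
# recorded per patient and drug for parameter-recovery testing.

#' Default background code vocabulary for the simulator
#'
#' Common community dispensing classes (BNF stems) and admission diagnoses
#' (ICD-10 categories) with relative sampling weights. Weights are scaled so
#' that admissions are rare: with the default event rate roughly 85% of
#' patients have no admission code, mirroring routine dispensing data where
#' most of the stream is medication events. Study drug classes are absent
#' here; their dispensing events are generated by the exposure model.
#'
#' @return data.frame with columns `code`, `code_system`, `freq`.
#' @export
defaultVocabSpec <- function() {
  rbind(
    data.frame(
      code = c("0103050", "0407010", "0301011", "0209000", "0501013",
               "0403030", "0407020", "0103010", "1001010", "0602010"),
      code_system = "BNF",
      freq = c(0.605, 0.501, 0.213, 0.211, 0.192,
               0.198, 0.288, 0.105, 0.163, 0.083)
    ),
    data.frame(
      code = c("H25", "N39", "J22", "I25", "J44", "A41",
               "C50", "R07", "R55", "I10", "E11"),
      code_system = "ICD10",
      freq = c(0.0050, 0.0045, 0.0033, 0.0034, 0.0027, 0.0028,
               0.0028, 0.0030, 0.0019, 0.0040, 0.0030)
    )
  )
}

#' Build a simulation configuration
#'
#' Assembles and validates a [SimulationConfig-class]. Defaults encode the
#' study conditions: two pandemic waves, 180-day follow-up, outcome
#' prevalence 9.5% with the observed case split across waves, exposure
#' prevalences near the reported dispensing frequencies, and moderately
#' confounded assignment.
#'
#' @param nPatients number of patients to simulate.
#' @param seed master seed; all randomness derives from it.
#' @param waveCount 1 or 2 waves.
#' @param followupDays outcome window length in days (default 180).
#' @param baseEventRate mean background events per lookback window
#'   (default 12).
#' @param vocabSpec background code vocabulary ([defaultVocabSpec()]).
#' @param confoundingStrength scaling of covariate effects in treatment
#'   assignment; 0 gives unconfounded (constant-propensity) assignment.
#' @param treatmentEffects named list of per-drug risk differences:
#'   constants, or functions of the demographics data.frame returning one
#'   value per patient. Names must match drug classes in `drugs`.
#' @param outcomeBasePrevalence target outcome prevalence under no
#'   treatment effect (default 0.095).
#' @param waveShare fraction of total incidence in wave 1 (default the
#'   observed case split 5344/28865).
#' @param treatmentPrevalence named target marginal exposure prevalences.
#' @param riskCoefs additive risk-difference coefficients of the baseline
#'   outcome model; scaled by `outcomeBasePrevalence / 0.095` so that the
#'   relative covariate effect is preserved across prevalence scenarios.
#' @param propensityCoefs log-odds coefficients of the assignment model.
#' @param clipTolerance rejection threshold for pre-clipping outcome
#'   probabilities outside `[0, 1]`.
#' @return a validated [SimulationConfig-class].
#' @export
simConfig <- function(nPatients,
                      seed = 1L,
                      waveCount = 2L,
                      followupDays = 180L,
                      baseEventRate = 12,
                      vocabSpec = defaultVocabSpec(),
                      confoundingStrength = 1,
                      treatmentEffects = list(ACEI = 0, BB = 0, CCB = 0,
                                              THZ = 0, STATIN = 0),
                      outcomeBasePrevalence = 0.095,
                      waveShare = 5344 / 28865,
                      treatmentPrevalence = c(ACEI = 0.195, BB = 0.211,
                                              CCB = 0.184, THZ = 0.06,
                                              STATIN = 0.25),
                      riskCoefs = NULL,
                      propensityCoefs = c(age_per_year = 0.04,
                                          male = 0.15,
                                          simd_per_decile = -0.05,
                                          diabetes = 0.5,
                                          comorbidity = 0.3),
                      clipTolerance = 1e-8) {
  if (is.null(riskCoefs)) {
    sc <- outcomeBasePrevalence / 0.095
    riskCoefs <- c(age_per_year = 0.0015, male = 0.01,
                   simd_per_decile = -0.002, diabetes = 0.02,
                   comorbidity = 0.004) * sc
  }
  methods::new("SimulationConfig",
    nPatients = as.integer(nPatients), seed = as.integer(seed),
    waveCount = as.integer(waveCount),
    followupDays = as.integer(followupDays),
    baseEventRate = baseEventRate, vocabSpec = vocabSpec,
    confoundingStrength = confoundingStrength,
    treatmentEffects = treatmentEffects,
    outcomeBasePrevalence = outcomeBasePrevalence,
    waveShare = waveShare, treatmentPrevalence = treatmentPrevalence,
    riskCoefs = riskCoefs, propensityCoefs = propensityCoefs,
    clipTolerance = clipTolerance)
}

# SIMD decile population shares used for sampling (most-deprived-heavy,
# reflecting an urban west-of-Scotland catchment).
.simdProbs <- c(0.228, 0.146, 0.092, 0.081, 0.068,
                0.065, 0.060, 0.074, 0.102, 0.085)

.ageMean <- 62
.ageSd <- 13
.ageMin <- 40
.ageMax <- 95
.femaleProb <- 0.562
.diabetesProb <- 0.081

# Analytic expectations of the covariates entering the linear predictors,
# used to centre intercepts so realised prevalences hit their targets
# without any data-dependent calibration.
.covariateMeans <- function(config) {
  icdShare <- with(config@vocabSpec,
                   sum(freq[code_system == "ICD10"]) / sum(freq))
  lambdaIcd <- config@baseEventRate * icdShare * config@waveCount
  k <- 0:50
  pk <- stats::dpois(k, lambdaIcd)
  list(
    age = truncNormMean(.ageMean, .ageSd, .ageMin, .ageMax),
    male = 1 - .femaleProb,
    simd = sum(.simdProbs * (1:10)),
    diabetes = .diabetesProb,
    comorb = lambdaIcd,
    logComorb = sum(log1p(k) * pk)
  )
}

.riskLinear <- function(coefs, age, male, simd, diabetes, comorb) {
  coefs[["age_per_year"]] * (age - 60) + coefs[["male"]] * male +
    coefs[["simd_per_decile"]] * (simd - 5.5) +
    coefs[["diabetes"]] * diabetes + coefs[["comorbidity"]] * comorb
}

.propLinear <- function(coefs, age, male, simd, diabetes, comorb) {
  coefs[["age_per_year"]] * (age - 60) + coefs[["male"]] * male +
    coefs[["simd_per_decile"]] * (simd - 5.5) +
    coefs[["diabetes"]] * diabetes + coefs[["comorbidity"]] * log1p(comorb)
}

# Per-drug treatment effect for one patient (demog is a one-row list).
.tauValue <- function(effect, demog) {
  if (is.function(effect)) effect(demog) else effect
}

#' Simulate a synthetic cohort with known ground truth
#'
#' Generates `nPatients` patients. Per patient: static covariates; a
#' Poisson number of background code events per wave lookback window with
#' codes drawn from the vocabulary and dates uniform over the window;
#' per-drug exposure drawn Bernoulli from a logistic propensity in age,
#' sex, SIMD, diabetes and admission-code count (scaled by
#' `confoundingStrength`), materialised as dispensing events of the drug's
#' BNF prefix in every lookback window; and the composite outcome drawn
#' Bernoulli with probability `clip(base_risk(x) + sum_d T_d * tau_d(x))`
#' within each wave's follow-up window. Identical configs (including seed)
#' give byte-identical tables, and per-patient random streams are derived
#' from the master seed by counter splitting, so increasing `nPatients`
#' leaves earlier patients unchanged.
#'
#' @param config a [SimulationConfig-class] from [simConfig()].
#' @param drugs list of [DrugClass-class] defining BNF prefixes for the
#'   treated drug classes (default [defaultDrugClasses()]).
#' @return a [SyntheticCohort-class].
#' @export
simulateCohort <- function(config, drugs = defaultDrugClasses()) {
  methods::validObject(config)
  waves <- defaultWaves(config@followupDays)[seq_len(config@waveCount)]
  drugNames <- names(config@treatmentEffects)
  missingDrugs <- setdiff(drugNames, vapply(drugs, function(d) d@name, ""))
  if (length(missingDrugs))
    stop("no DrugClass definition for: ", paste(missingDrugs, collapse = ", "))
  drugs <- drugs[match(drugNames, vapply(drugs, function(d) d@name, ""))]

  vs <- config@vocabSpec
  vw <- vs$freq / sum(vs$freq)
  nCodes <- nrow(vs)
  mu <- .covariateMeans(config)

  # Analytic intercepts: outcome model intercept so E[p] hits the target
  # prevalence, and per-drug propensity intercepts so mean assignment is
  # near the target exposure prevalence.
  b0 <- config@outcomeBasePrevalence -
    .riskLinear(config@riskCoefs, mu$age, mu$male, mu$simd, mu$diabetes,
                mu$comorb)
  etaMean <- config@propensityCoefs[["age_per_year"]] * (mu$age - 60) +
    config@propensityCoefs[["male"]] * mu$male +
    config@propensityCoefs[["simd_per_decile"]] * (mu$simd - 5.5) +
    config@propensityCoefs[["diabetes"]] * mu$diabetes +
    config@propensityCoefs[["comorbidity"]] * mu$logComorb
  a0 <- stats::qlogis(config@treatmentPrevalence[drugNames]) -
    config@confoundingStrength * etaMean

  n <- config@nPatients
  nd <- length(drugNames)
  share <- if (config@waveCount == 2L) config@waveShare else 1

  age <- male <- simd <- diab <- numeric(n)
  evId <- evCode <- evSys <- vector("list", n)
  evDate <- vector("list", n)
  gMat <- matrix(NA_real_, n, nd)
  tMat <- matrix(0L, n, nd)
  pT <- matrix(NA_real_, n, nd)
  pC <- matrix(NA_real_, n, nd)
  testD <- hospD <- deathD <- rep(as.Date(NA), n)
  preclipLo <- Inf
  preclipHi <- -Inf

  suffix7 <- c("AAAA", "ABAA", "ACAA", "BAAA", "BBAA")
  lookStarts <- lapply(waves, function(w) w@lookbackStart)
  lookLens <- vapply(waves, function(w)
    as.numeric(w@lookbackEnd - w@lookbackStart), 0)

  for (i in seq_len(n)) {
    set.seed(deriveSeed(config@seed, i))
    age[i] <- rtruncNorm(1, .ageMean, .ageSd, .ageMin, .ageMax)
    male[i] <- as.integer(stats::runif(1) > .femaleProb)
    simd[i] <- sample.int(10, 1, prob = .simdProbs)
    diab[i] <- as.integer(stats::runif(1) < .diabetesProb)

    codes <- character(0); sys <- character(0); dates <- numeric(0)
    for (w in seq_along(waves)) {
      nev <- stats::rpois(1, config@baseEventRate)
      if (nev > 0) {
        idx <- sample.int(nCodes, nev, replace = TRUE, prob = vw)
        codes <- c(codes, vs$code[idx])
        sys <- c(sys, vs$code_system[idx])
        dates <- c(dates, as.numeric(lookStarts[[w]]) +
                     floor(stats::runif(nev, 0, lookLens[w])))
      }
      if (diab[i] == 1L) {
        ndm <- 1L + stats::rpois(1, 1)
        codes <- c(codes, rep("0601022B0AAAA", ndm))
        sys <- c(sys, rep("BNF", ndm))
        dates <- c(dates, as.numeric(lookStarts[[w]]) +
                     floor(stats::runif(ndm, 0, lookLens[w])))
      }
    }
    comorb <- sum(sys == "ICD10")

    eta <- .propLinear(config@propensityCoefs, age[i], male[i], simd[i],
                       diab[i], comorb)
    g <- stats::plogis(a0 + config@confoundingStrength * eta)
    gMat[i, ] <- g
    tMat[i, ] <- as.integer(stats::runif(nd) < g)

    for (d in seq_len(nd)) {
      if (tMat[i, d] == 1L) {
        prefixes <- drugs[[d]]@bnfPrefixes
        for (w in seq_along(waves)) {
          ndisp <- 1L + stats::rpois(1, 1.2)
          pref <- prefixes[sample.int(length(prefixes), ndisp,
                                      replace = TRUE)]
          suf <- ifelse(nchar(pref) >= 9,
                        "AA",
                        suffix7[sample.int(length(suffix7), ndisp,
                                           replace = TRUE)])
          codes <- c(codes, paste0(pref, suf))
          sys <- c(sys, rep("BNF", ndisp))
          dates <- c(dates, as.numeric(lookStarts[[w]]) +
                       floor(stats::runif(ndisp, 0, lookLens[w])))
        }
      }
    }
    evCode[[i]] <- codes
    evSys[[i]] <- sys
    evDate[[i]] <- dates

    demogRow <- list(age = age[i], sex = if (male[i]) "M" else "F",
                     simd_decile = simd[i], diabetes = diab[i])
    tau <- vapply(config@treatmentEffects, .tauValue, 0, demog = demogRow)
    base <- b0 + .riskLinear(config@riskCoefs, age[i], male[i], simd[i],
                             diab[i], comorb)
    tauSum <- sum(tau * tMat[i, ])

    q1pre <- share * base + tauSum
    q2base <- if (config@waveCount == 2L)
      (base - share * base) / (1 - share * base) else NA_real_
    q2pre <- if (config@waveCount == 2L) q2base + tauSum else NA_real_
    preclipLo <- min(preclipLo, q1pre, q2pre, na.rm = TRUE)
    preclipHi <- max(preclipHi, q1pre, q2pre, na.rm = TRUE)

    # Ground truth on the analysis window: wave 1 when simulating a single
    # wave, otherwise the (larger) wave-2 window.
    refBase <- if (config@waveCount == 2L) q2base else base
    otherTau <- tauSum - tau * tMat[i, ]
    pT[i, ] <- clip01(refBase + otherTau + tau)
    pC[i, ] <- clip01(refBase + otherTau)

    q1 <- clip01(q1pre)
    y1 <- stats::runif(1) < q1
    yWave <- 0L
    if (y1) {
      yWave <- 1L
    } else if (config@waveCount == 2L) {
      if (stats::runif(1) < clip01(q2pre)) yWave <- 2L
    }
    if (yWave > 0L) {
      fw <- waves[[yWave]]
      eventDay <- floor(stats::runif(1, 0, config@followupDays))
      # The earliest component is always a positive test; a hospitalisation
      # and/or COVID death may follow within days of it.
      testD[i] <- fw@followupStart + eventDay
      if (stats::runif(1) < 0.20)
        hospD[i] <- testD[i] + floor(stats::runif(1, 0, 11))
      if (stats::runif(1) < 0.04)
        deathD[i] <- testD[i] + floor(stats::runif(1, 5, 31))
    }
  }

  tol <- config@clipTolerance
  if (preclipLo < -tol || preclipHi > 1 + tol)
    stop(sprintf(paste0("mis-specified scenario: pre-clipping outcome ",
                        "probabilities span [%.4f, %.4f]"),
                 preclipLo, preclipHi))

  ids <- sprintf("P%06d", seq_len(n))
  demographics <- data.frame(
    patient_id = ids, age = age, sex = ifelse(male == 1, "M", "F"),
    simd_decile = as.integer(simd), diabetes = as.integer(diab),
    stringsAsFactors = FALSE)

  nev <- lengths(evCode)
  events <- data.frame(
    patient_id = rep(ids, nev),
    event_date = as.Date(unlist(evDate), origin = "1970-01-01"),
    code = unlist(evCode),
    code_system = unlist(evSys),
    stringsAsFactors = FALSE)
  events <- events[order(events$patient_id, events$event_date,
                         events$code_system, events$code), ]
  rownames(events) <- NULL

  outcomes <- data.frame(
    patient_id = ids, test_date = testD, hosp_date = hospD,
    death_date = deathD, stringsAsFactors = FALSE)

  groundTruth <- data.frame(
    patient_id = rep(ids, each = nd),
    drug = rep(drugNames, n),
    true_propensity = as.vector(t(gMat)),
    true_ite = as.vector(t(pT - pC)),
    true_outcome_prob_treated = as.vector(t(pT)),
    true_outcome_prob_control = as.vector(t(pC)),
    exposed = as.vector(t(tMat)),
    stringsAsFactors = FALSE)

  methods::new("SyntheticCohort", demographics = demographics,
               events = events, outcomes = outcomes,
               groundTruth = groundTruth, config = config)
}

#' Write the simulator's CSV interface files
#'
#' Writes `events.csv`, `demographics.csv`, `outcomes.csv` and (simulation
#' mode only) `ground_truth.csv` into `dir`, dates ISO-8601, empty fields
#' for absent outcome dates.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeCohortTables <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("events.csv", "demographics.csv",
                            "outcomes.csv", "ground_truth.csv"))
  utils::write.csv(cohort@events, paths[1], row.names = FALSE, na = "")
  utils::write.csv(cohort@demographics, paths[2], row.names = FALSE,
                   na = "")
  utils::write.csv(cohort@outcomes, paths[3], row.names = FALSE, na = "")
  gt <- cohort@groundTruth[, c("patient_id", "drug", "true_propensity",
                               "true_ite")]
  utils::write.csv(gt, paths[4], row.names = FALSE, na = "")
  invisible(paths)
}

#' @describeIn SyntheticCohort event table accessor
#' @param object a `SyntheticCohort`.
#' @export
setMethod("cohortEvents", "SyntheticCohort", function(object) object@events)

#' @describeIn SyntheticCohort demographics accessor
#' @export
setMethod("cohortDemographics", "SyntheticCohort",
          function(object) object@demographics)

#' @describeIn SyntheticCohort outcome-dates accessor
#' @export
setMethod("cohortOutcomes", "SyntheticCohort",
          function(object) object@outcomes)

#' @describeIn SyntheticCohort ground-truth accessor
#' @export
setMethod("groundTruth", "SyntheticCohort",
          function(object) object@groundTruth)

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", nrow(object@demographics), "patients,",
      nrow(object@events), "events,",
      length(unique(object@groundTruth$drug)), "drug classes\n")
})

#' Canonical parameter-recovery scenarios
#'
#' Fixed simulation configurations used for estimator validation and by
#' the acceptance script: `"null"` (two drugs, zero effect, confounded
#' assignment, outcome prevalence 9.5%), `"constant"` (one drug, constant
#' risk difference -0.10 on a base prevalence of 0.30 so no clipping
#' occurs), and `"heterogeneous"` (one drug whose effect declines linearly
#' with age, -0.05 at age 60 and -0.003 per additional year). All are
#' single-wave scenarios so the constant-effect ground truth is exact.
#'
#' @param type scenario name.
#' @param nPatients cohort size (default 20000).
#' @param seed master seed.
#' @return a [SimulationConfig-class].
#' @export
scenarioConfig <- function(type = c("null", "constant", "heterogeneous"),
                           nPatients = 20000L, seed = 1L) {
  type <- match.arg(type)
  switch(type,
    null = simConfig(nPatients, seed = seed, waveCount = 1L,
                     confoundingStrength = 1,
                     treatmentEffects = list(ACEI = 0, BB = 0),
                     treatmentPrevalence = c(ACEI = 0.195, BB = 0.211)),
    constant = simConfig(nPatients, seed = seed, waveCount = 1L,
                         outcomeBasePrevalence = 0.30,
                         treatmentEffects = list(ACEI = -0.10),
                         treatmentPrevalence = c(ACEI = 0.2)),
    heterogeneous = simConfig(
      nPatients, seed = seed, waveCount = 1L,
      outcomeBasePrevalence = 0.30,
      treatmentEffects = list(
        ACEI = function(demog) -0.05 - 0.003 * (demog$age - 60)),
      treatmentPrevalence = c(ACEI = 0.2)))
}

#' Transformer configuration used in the recovery scenarios
#'
#' A compact architecture sized for the simulated cohorts (32-dim
#' embeddings, 4 heads, 2 layers, 64-dim feed-forward, 32-event
#' sequences, 10 epochs with patience 2).
#'
#' @param seed integer seed.
#' @return a [TransformerConfig-class].
#' @export
scenarioTransformerConfig <- function(seed = 1L) {
  transformerConfig(embedDim = 32L, nHeads = 4L, nLayers = 2L,
                    ffDim = 64L, maxLen = 32L, epochs = 10L,
                    patience = 2L, batchSize = 128L, seed = seed)
}
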