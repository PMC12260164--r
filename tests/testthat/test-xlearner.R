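# The X-learner algebra is checked against hand computation with frozen
# sub-models, then the meta-learner's statistical behaviour on simulated
# cohorts with known ground truth.

# A six-patient cohort with hand-specified sub-models keyed off the raw
# SIMD column of the static features.
oracleWorld <- function() {
  dm <- data.frame(patient_id = sprintf("O%03d", 1:6),
                   age = c(45, 52, 60, 68, 75, 83),
                   sex = c("F", "M", "F", "M", "F", "M"),
                   simd_decile = 1:6, diabetes = c(0L, 1L, 0L, 1L, 0L, 1L),
                   stringsAsFactors = FALSE)
  labels <- data.frame(patient_id = dm$patient_id, wave_id = 1L,
                       Y = c(1L, 0L, 1L, 1L, 0L, 0L),
                       event_day = c(20L, 180L, 40L, 10L, 180L, 180L),
                       ACEI = c(1L, 1L, 1L, 0L, 0L, 0L),
                       stringsAsFactors = FALSE)
  cohort <- methods::new("LabeledCohort", labels = labels,
                         exclusions = data.frame(),
                         undersamplingRatio = NA_real_,
                         waves = defaultWaves()[1],
                         drugs = list(defaultDrugClasses()$ACEI))
  events <- makeEvents(character(0), as.Date(character(0)), character(0),
                       character(0))
  mu0 <- function(enc) 0.05 * staticFeatures(enc)[, "simd"]
  mu1 <- function(enc) 0.10 * staticFeatures(enc)[, "simd"]
  tau0 <- function(X) 0.01 * X[, "simd"]
  tau1 <- function(X) 0.04 * X[, "simd"]
  g <- function(X) stats::plogis((X[, "simd"] - 3.5) / 2)
  list(dm = dm, labels = labels, cohort = cohort, events = events,
       mu0 = mu0, mu1 = mu1, tau0 = tau0, tau1 = tau1, g = g)
}

fitOracle <- function(ow, epsilon = 0.01) {
  fitXLearner(
    ow$cohort, "ACEI", ow$events, ow$dm,
    baseLearner = function(encoded, y, seed) {
      # the factory sees only its own arm; decide which surface by size
      if (length(y) == 3 && all(y == c(1L, 0L, 1L)))
        functionRiskModel(ow$mu1)
      else functionRiskModel(ow$mu0)
    },
    effectLearner = local({
      call <- 0L
      function(X, d, seed) {
        call <<- call + 1L
        if (call == 1L) ow$tau1 else ow$tau0  # treated arm is fitted first
      }
    }),
    propensityLearner = function(X, t, seed) ow$g,
    minArmSize = 1L, epsilon = epsilon, seed = 7L)
}

test_that("stage-2 imputations equal the counterfactual formulas exactly", {
  ow <- oracleWorld()
  fit <- fitOracle(ow)
  # treated: D1 = Y - mu0(x); controls: D0 = mu1(x) - Y
  d1Hand <- ow$labels$Y[1:3] - 0.05 * (1:3)
  d0Hand <- 0.10 * (4:6) - ow$labels$Y[4:6]
  imp <- fit@imputed
  expect_identical(imp$D[imp$arm == "treated"], d1Hand)
  expect_identical(imp$D[imp$arm == "control"], d0Hand)
  # the printed examples: Y=1, mu0 = 0.3 -> 0.7; Y=0, mu1 = 0.45 -> 0.45
  expect_equal(1 - 0.3, 0.7)
  expect_equal(0.45 - 0, 0.45)
})

test_that("tau_hat matches the propensity-weighted hand computation", {
  ow <- oracleWorld()
  fit <- fitOracle(ow)
  ite <- estimateIte(fit, ow$dm$patient_id, ow$events, ow$dm)
  s <- 1:6
  gH <- pmin(1 - 0.01, pmax(0.01, stats::plogis((s - 3.5) / 2)))
  tauHand <- gH * (0.01 * s) + (1 - gH) * (0.04 * s)
  expect_equal(ite$tau_hat, tauHand, tolerance = 1e-12)
  expect_equal(ite$g, gH, tolerance = 1e-12)
  ate <- estimateAte(ite)
  expect_equal(ate$ate, mean(tauHand), tolerance = 1e-12)
  expect_true(ate$ate >= min(ite$tau_hat) && ate$ate <= max(ite$tau_hat))
})

test_that("the propensity weight interpolates the effect surfaces", {
  # g = 0, 1 and 0.5 endpoints, and constancy when tau0 == tau1
  comb <- function(g, t0, t1) pmin(1, pmax(-1, g * t0 + (1 - g) * t1))
  expect_equal(comb(0.5, 0.2, 0.4), 0.3)
  expect_equal(comb(0, 0.2, 0.4), 0.4)   # tau1 only
  expect_equal(comb(1, 0.2, 0.4), 0.2)   # tau0 only
  expect_equal(comb(c(0.1, 0.6, 0.95), 0.25, 0.25), rep(0.25, 3))
})

test_that("ITEs stay within the risk-difference bounds", {
  ow <- oracleWorld()
  fit <- fitXLearner(
    ow$cohort, "ACEI", ow$events, ow$dm,
    baseLearner = function(encoded, y, seed)
      functionRiskModel(function(enc) rep(0.5, nrow(enc@tokenIds))),
    effectLearner = function(X, d, seed) function(Xn) rep(5, nrow(Xn)),
    propensityLearner = function(X, t, seed) function(Xn)
      rep(0.5, nrow(Xn)),
    minArmSize = 1L, seed = 7L)
  ite <- estimateIte(fit, ow$dm$patient_id, ow$events, ow$dm)
  expect_true(all(ite$tau_hat >= -1 & ite$tau_hat <= 1))
})

test_that("ATE aggregation is the arithmetic mean with dispersion", {
  ite <- data.frame(patient_id = c("a", "b", "c"), drug = "ACEI",
                    tau_hat = c(0.1, -0.3, 0.2), g = 0.5, tau0 = 0,
                    tau1 = 0, stringsAsFactors = FALSE)
  ate <- estimateAte(ite)
  expect_equal(ate$ate, 0)
  same <- ite
  same$tau_hat <- rep(0.07, 3)
  ateSame <- estimateAte(same)
  expect_equal(ateSame$ate, 0.07)
  expect_equal(ateSame$sd, 0)
  expect_error(estimateAte(ite[0, ]), "empty")
})

test_that("degenerate arms abort with a diagnostic", {
  ow <- oracleWorld()
  expect_error(
    fitXLearner(ow$cohort, "ACEI", ow$events, ow$dm, minArmSize = 10L),
    "arm too small")
  badLabels <- ow$labels
  badLabels$Y[1:3] <- 1L  # treated arm single-class
  badCohort <- methods::new("LabeledCohort", labels = badLabels,
                            exclusions = data.frame(),
                            undersamplingRatio = NA_real_,
                            waves = defaultWaves()[1],
                            drugs = list(defaultDrugClasses()$ACEI))
  expect_error(
    fitXLearner(badCohort, "ACEI", ow$events, ow$dm, minArmSize = 1L),
    "single-class")
})

test_that("under no confounding and no effect the ATE is near zero", {
  sim <- simulateCohort(simConfig(
    20000, seed = 51, waveCount = 1L, confoundingStrength = 0,
    treatmentEffects = list(ACEI = 0),
    treatmentPrevalence = c(ACEI = 0.2)))
  cohort <- buildCohort(cohortEvents(sim), cohortDemographics(sim),
                        cohortOutcomes(sim), waves = defaultWaves()[1])
  lb <- cohortLabels(cohort)
  fit <- fitXLearner(cohort, "ACEI", cohortEvents(sim),
                     cohortDemographics(sim), baseLearner = "logistic",
                     maxLen = 32L, seed = 5L)
  ite <- estimateIte(fit, lb$patient_id, cohortEvents(sim),
                     cohortDemographics(sim))
  expect_lt(abs(estimateAte(ite)$ate), 0.02)
})

test_that("opposite constant effects are recovered with opposite signs", {
  signs <- vapply(1:20, function(rep) {
    ates <- vapply(c(-0.10, +0.10), function(tau) {
      cfg <- simConfig(2000, seed = 100 + rep, waveCount = 1L,
                       outcomeBasePrevalence = 0.30,
                       treatmentEffects = list(ACEI = tau),
                       treatmentPrevalence = c(ACEI = 0.25))
      sim <- simulateCohort(cfg)
      cohort <- buildCohort(cohortEvents(sim), cohortDemographics(sim),
                            cohortOutcomes(sim),
                            waves = defaultWaves()[1])
      lb <- cohortLabels(cohort)
      fit <- fitXLearner(cohort, "ACEI", cohortEvents(sim),
                         cohortDemographics(sim),
                         baseLearner = "logistic", maxLen = 32L,
                         seed = rep)
      ite <- estimateIte(fit, lb$patient_id, cohortEvents(sim),
                         cohortDemographics(sim))
      estimateAte(ite)$ate
    }, 0)
    ates[1] < 0 && ates[2] > 0
  }, TRUE)
  expect_gte(mean(signs), 0.95)
})
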