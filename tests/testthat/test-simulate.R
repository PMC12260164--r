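test_that("identical configs give byte-identical cohorts", {
  a <- simulateCohort(simConfig(300, seed = 4))
  b <- simulateCohort(simConfig(300, seed = 4))
  expect_identical(cohortEvents(a), cohortEvents(b))
  expect_identical(cohortDemographics(a), cohortDemographics(b))
  expect_identical(cohortOutcomes(a), cohortOutcomes(b))
  expect_identical(groundTruth(a), groundTruth(b))
})

test_that("growing the cohort leaves earlier patients' streams unchanged", {
  a <- simulateCohort(simConfig(100, seed = 4))
  b <- simulateCohort(simConfig(160, seed = 4))
  ids <- sprintf("P%06d", 1:100)
  ea <- cohortEvents(a)
  eb <- cohortEvents(b)
  eb <- eb[eb$patient_id %in% ids, ]
  rownames(ea) <- rownames(eb) <- NULL
  expect_identical(ea, eb)
  expect_identical(cohortDemographics(a),
                   cohortDemographics(b)[1:100, ])
})

test_that("events are sorted and codes follow their dialects", {
  w <- smallWorld()
  ev <- w$events
  o <- order(ev$patient_id, ev$event_date, ev$code_system, ev$code)
  expect_identical(o, seq_len(nrow(ev)))
  bnf <- ev$code[ev$code_system == "BNF"]
  icd <- ev$code[ev$code_system == "ICD10"]
  expect_true(all(grepl("^[0-9]{7}", bnf)))
  expect_true(all(grepl("^[A-Z][0-9]+", icd)))
})

test_that("misspecified effect scenarios are rejected before clipping", {
  cfg <- simConfig(100, seed = 1, waveCount = 1L,
                   treatmentEffects = list(ACEI = -0.5),
                   treatmentPrevalence = c(ACEI = 0.2))
  expect_error(simulateCohort(cfg), "mis-specified")
  expect_error(simConfig(100, outcomeBasePrevalence = 1.2), "revalence")
})

test_that("zero confounding gives treatment unrelated to covariates", {
  sim <- simulateCohort(simConfig(
    10000, seed = 21, waveCount = 1L, confoundingStrength = 0,
    treatmentEffects = list(ACEI = 0),
    treatmentPrevalence = c(ACEI = 0.2)))
  gt <- groundTruth(sim)
  dm <- cohortDemographics(sim)
  expect_true(stats::sd(gt$true_propensity) == 0)
  tr <- gt$exposed[match(dm$patient_id, gt$patient_id)]
  expect_lt(abs(stats::cor(tr, dm$age)), 0.05)
  expect_lt(abs(stats::cor(tr, dm$simd_decile)), 0.05)
  expect_lt(abs(stats::cor(tr, dm$diabetes)), 0.05)
})

test_that("null-effect ground truth has exactly equal arms", {
  w <- smallWorld()
  gt <- groundTruth(w$sim)
  expect_identical(gt$true_outcome_prob_treated,
                   gt$true_outcome_prob_control)
  expect_true(all(gt$true_ite == 0))
})

test_that("constant effect is reproduced exactly in the ground truth and
           approximately in propensity-stratified risk differences", {
  sim <- simulateCohort(scenarioConfig("constant", 20000L, seed = 1))
  gt <- groundTruth(sim)
  expect_equal(mean(gt$true_ite), -0.10, tolerance = 1e-12)
  expect_equal(range(gt$true_ite), c(-0.10, -0.10), tolerance = 1e-12)
  # stratify on the true propensity and average arm contrasts
  oc <- cohortOutcomes(sim)
  y <- as.integer(!is.na(oc$test_date[match(gt$patient_id,
                                            oc$patient_id)]))
  strat <- cut(gt$true_propensity, stats::quantile(gt$true_propensity,
                                                   0:5 / 5),
               include.lowest = TRUE)
  rd <- vapply(split(data.frame(y = y, t = gt$exposed), strat),
               function(s) mean(s$y[s$t == 1]) - mean(s$y[s$t == 0]), 0)
  n_s <- vapply(split(gt$exposed, strat), length, 0L)
  expect_lt(abs(sum(rd * n_s) / sum(n_s) - (-0.10)), 0.02)
})

test_that("observed prevalence matches the configured 9.5% target", {
  sim <- simulateCohort(simConfig(50000, seed = 3))
  oc <- cohortOutcomes(sim)
  prev <- mean(!is.na(oc$test_date))
  expect_lt(abs(prev - 0.095), 0.005)
})

test_that("background event counts follow the configured Poisson rate", {
  sim <- simulateCohort(simConfig(
    10000, seed = 31, waveCount = 1L,
    treatmentEffects = list(ACEI = 0),
    treatmentPrevalence = c(ACEI = 0.2)))
  dm <- cohortDemographics(sim)
  gt <- groundTruth(sim)
  ev <- cohortEvents(sim)
  # restrict to patients with no exposure and no diabetes: their event
  # stream is exactly Poisson(baseEventRate)
  unexposed <- gt$patient_id[gt$exposed == 0]
  pure <- intersect(unexposed, dm$patient_id[dm$diabetes == 0])
  cnt <- table(factor(ev$patient_id, levels = pure))
  lambda <- 12
  k <- 0:40
  pk <- stats::dpois(k, lambda)
  obs <- tabulate(factor(pmin(as.integer(cnt), 40) + 1, levels = 1:41),
                  nbins = 41)
  # merge tail bins with small expectation
  keep <- which(pk * length(pure) >= 5)
  lo <- min(keep); hi <- max(keep)
  obsM <- c(sum(obs[seq_len(lo - 1)]), obs[lo:hi],
            sum(obs[seq.int(hi + 1, 41)]))
  pM <- c(sum(pk[seq_len(lo - 1)]), pk[lo:hi], 1 - sum(pk[seq_len(hi)]))
  gof <- suppressWarnings(stats::chisq.test(obsM, p = pM))
  expect_gt(gof$p.value, 0.01)
})

test_that("the CSV interface writes ISO dates and the ground-truth file", {
  w <- smallWorld()
  dir <- withr::local_tempdir()
  paths <- writeCohortTables(w$sim, dir)
  expect_true(all(file.exists(paths)))
  ev <- utils::read.csv(paths[1])
  expect_true(all(grepl("^\\d{4}-\\d{2}-\\d{2}$", ev$event_date)))
  gt <- utils::read.csv(paths[4])
  expect_identical(names(gt), c("patient_id", "drug", "true_propensity",
                                "true_ite"))
})
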