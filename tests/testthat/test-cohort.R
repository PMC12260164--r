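test_that("eligibility keeps age >= 40 with complete demographics", {
  dm <- data.frame(
    patient_id = c("a", "b", "c", "d", "e"),
    age = c(39.9, 40.0, 70, 55, NA),
    sex = c("F", "M", "F", "", "M"),
    simd_decile = c(3, 5, NA, 2, 4),
    stringsAsFactors = FALSE)
  res <- filterEligible(dm)
  expect_identical(res$patients$patient_id, "b")
  lg <- res$log
  expect_equal(lg$n[lg$reason == "age < 40"], 1)
  expect_equal(lg$n[lg$reason == "missing SIMD"], 1)
  expect_equal(lg$n[lg$reason == "missing sex"], 1)
  expect_equal(lg$n[lg$reason == "missing age"], 1)
  expect_error(filterEligible(NULL), "demographics")
})

test_that("exposure uses half-open lookback windows and BNF prefixes", {
  wave <- defaultWaves()[[1]]
  acei <- defaultDrugClasses()$ACEI
  statin <- defaultDrugClasses()$STATIN
  evStart <- makeEvents("a", "2019-10-01", "0205051ABAA")
  evEnd <- makeEvents("a", "2020-04-01", "0205051ABAA")
  expect_identical(defineExposure(evStart, acei, wave), 1L)
  expect_identical(defineExposure(evEnd, acei, wave), 0L)
  evStatin <- makeEvents("a", "2020-01-15", "0212000B0AAAB")
  expect_identical(defineExposure(evStatin, statin, wave), 1L)
  expect_identical(defineExposure(evStatin, acei, wave), 0L)
  expect_identical(defineExposure(evStatin[0, ], acei, wave), 0L)
  # ICD-10 records never count as dispensing exposure
  evIcd <- makeEvents("a", "2020-01-15", "I10")
  expect_identical(defineExposure(evIcd, acei, wave), 0L)
})

test_that("adding dispensing events never revokes exposure", {
  wave <- defaultWaves()[[1]]
  drug <- defaultDrugClasses()$BB
  withr::with_seed(8, {
    for (i in 1:25) {
      n <- sample(0:6, 1)
      days <- sample(0:250, n + 1, replace = TRUE)
      codes <- sample(c("0204000AB", "0103050AA", "0206020XX"), n + 1,
                      replace = TRUE)
      ev <- makeEvents(rep("a", n), as.Date("2019-10-01") + days[seq_len(n)],
                       codes[seq_len(n)])
      before <- defineExposure(ev, drug, wave)
      evMore <- rbind(ev, makeEvents("a", as.Date("2019-10-01") + days[n + 1],
                                     codes[n + 1]))
      expect_gte(defineExposure(evMore, drug, wave), before)
    }
  })
})

test_that("the composite outcome takes the earliest event in the window", {
  wave <- defaultWaves()[[1]]
  fs <- wave@followupStart
  row <- data.frame(test_date = fs + 40, hosp_date = fs + 20,
                    death_date = as.Date(NA))
  out <- deriveOutcome(row, wave)
  expect_identical(out[c("Y", "event_day")], list(Y = 1L, event_day = 20L))
  none <- deriveOutcome(data.frame(test_date = as.Date(NA),
                                   hosp_date = as.Date(NA),
                                   death_date = as.Date(NA)), wave)
  expect_identical(none[c("Y", "event_day")],
                   list(Y = 0L, event_day = 180L))
  late <- deriveOutcome(data.frame(test_date = as.Date(NA),
                                   hosp_date = as.Date(NA),
                                   death_date = fs + 200), wave)
  expect_identical(late[c("Y", "event_day")],
                   list(Y = 0L, event_day = 180L))
  prev <- deriveOutcome(data.frame(test_date = fs - 3,
                                   hosp_date = as.Date(NA),
                                   death_date = as.Date(NA)), wave)
  expect_true(prev$prevalent)
  # pure function: identical calls agree
  expect_identical(deriveOutcome(row, wave), deriveOutcome(row, wave))
})

test_that("undersampling keeps all cases, partitions the pool, and hits
           the binomial retention rate", {
  expect_equal(signif(undersamplingRatio(5344, 23521), 5), 0.22720)
  pool <- data.frame(
    patient_id = sprintf("p%05d", 1:10500),
    Y = rep(c(1L, 0L), c(500, 10000)),
    age = 55, sex = "F", simd_decile = 4, stringsAsFactors = FALSE)
  us <- undersampleNegatives(pool, casesWave1 = 1, casesWave2 = 4,
                             seed = 5)
  expect_equal(us$ratio, 0.25)
  expect_equal(sum(us$cohort$Y), 500)          # cases preserved
  expect_equal(sum(us$excluded$Y), 0)
  # partition: union equals pool, intersection empty
  expect_setequal(c(us$cohort$patient_id, us$excluded$patient_id),
                  pool$patient_id)
  expect_length(intersect(us$cohort$patient_id, us$excluded$patient_id), 0)
  kept <- sum(us$cohort$Y == 0)
  expect_gte(kept, stats::qbinom(0.005, 10000, 0.25))
  expect_lte(kept, stats::qbinom(0.995, 10000, 0.25))
  # deterministic given the seed
  us2 <- undersampleNegatives(pool, 1, 4, seed = 5)
  expect_identical(us$cohort, us2$cohort)
  expect_warning(undersampleNegatives(pool, 5, 4, seed = 1), "ratio")
})

test_that("two-wave cohort construction assigns each patient one wave", {
  sim <- simulateCohort(simConfig(3000, seed = 17))
  cohort <- buildCohort(cohortEvents(sim), cohortDemographics(sim),
                        cohortOutcomes(sim), seed = 2)
  lb <- cohortLabels(cohort)
  expect_equal(anyDuplicated(lb$patient_id), 0)
  expect_setequal(unique(lb$wave_id), c(1L, 2L))
  # conservation: eligible patients all land in exactly one wave
  expect_equal(nrow(lb), nrow(cohortDemographics(sim)))
  # wave-1 keeps all its cases; wave-2 pool is wave-1 negatives only
  expect_true(cohort@undersamplingRatio < 1)
  w2 <- lb[lb$wave_id == 2L, ]
  expect_true(all(c("ACEI", "BB", "CCB", "THZ", "STATIN") %in% names(lb)))
  # undersampling lifts wave-1 prevalence well above its raw value
  rawPrev <- sum(lb$Y[lb$wave_id == 1L]) / nrow(lb)
  expect_gt(mean(lb$Y[lb$wave_id == 1L]), 2 * rawPrev)
})

test_that("cohort summaries report counts, medians and percentages", {
  w <- smallWorld()
  tab <- summarizeCohort(w$cohort, topCodes = w$events, topK = 3L)
  expect_true(all(c("N", "age", "sex", "simd_decile", "diabetes",
                    "incident_outcome", "top_code") %in% tab$section))
  N <- tab$n[tab$section == "N"]
  nf <- tab$n[tab$section == "sex" & tab$level == "F"]
  expect_equal(tab$pct[tab$section == "sex" & tab$level == "F"],
               percentOf(nf, N))
  single <- summarizeCohort(w$cohort@labels[1, , drop = FALSE])
  expect_equal(single$n[single$section == "N"], 1)
  expect_true(single$pct[single$section == "incident_outcome"] %in%
                c(0, 100))
})
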