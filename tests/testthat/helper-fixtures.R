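# Shared in-code fixtures. Everything is generated programmatically; no
# data files are read.

# Small single-wave simulated world, cached per test run.
smallWorld <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulateCohort(simConfig(
        400, seed = 99, waveCount = 1L,
        treatmentEffects = list(ACEI = 0, BB = 0),
        treatmentPrevalence = c(ACEI = 0.3, BB = 0.3)))
      cohort <- buildCohort(cohortEvents(sim), cohortDemographics(sim),
                            cohortOutcomes(sim), waves = defaultWaves()[1])
      cache <<- list(sim = sim, cohort = cohort,
                     demographics = cohortDemographics(sim),
                     events = cohortEvents(sim),
                     outcomes = cohortOutcomes(sim),
                     labels = cohortLabels(cohort),
                     wave = defaultWaves()[[1]])
    }
    cache
  }
})

# Hand-rolled event table builder.
makeEvents <- function(patient_id, event_date, code,
                       code_system = ifelse(grepl("^[A-Z]", code),
                                            "ICD10", "BNF")) {
  data.frame(patient_id = patient_id, event_date = as.Date(event_date),
             code = code, code_system = code_system,
             stringsAsFactors = FALSE)
}

makeDemographics <- function(n, age = 60, sex = "F", simd = 5,
                             diabetes = 0L) {
  data.frame(patient_id = sprintf("X%03d", seq_len(n)),
             age = rep_len(age, n), sex = rep_len(sex, n),
             simd_decile = rep_len(simd, n),
             diabetes = rep_len(diabetes, n), stringsAsFactors = FALSE)
}

# Tiny encoded batch built directly from hand data.
encodeTiny <- function(events, demographics, maxLen = 8L,
                       excludePrefixes = character(),
                       wave = defaultWaves()[[1]], vocab = NULL) {
  if (is.null(vocab)) vocab <- buildVocabulary(events)
  encodePatients(demographics$patient_id, events, demographics, wave,
                 vocab, maxLen = maxLen, excludePrefixes = excludePrefixes)
}
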