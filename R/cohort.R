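# Cohort construction: eligibility, BNF-prefix exposure, composite
# outcome, wave splitting and stratified undersampling of negatives.

#' Construct a wave definition
#'
#' @param waveId 1 or 2.
#' @param lookbackStart,lookbackEnd lookback window (half-open), coercible
#'   to `Date`.
#' @param followupDays outcome window length (default 180).
#' @return a [WaveDefinition-class]; follow-up starts at `lookbackEnd`.
#' @export
waveDefinition <- function(waveId, lookbackStart, lookbackEnd,
                           followupDays = 180L) {
  methods::new("WaveDefinition", waveId = as.integer(waveId),
               lookbackStart = as.Date(lookbackStart),
               lookbackEnd = as.Date(lookbackEnd),
               followupStart = as.Date(lookbackEnd),
               followupDays = as.integer(followupDays))
}

#' Default study waves
#'
#' Wave 1: lookback 2019-10-01 to 2020-04-01, follow-up from 2020-04-01.
#' Wave 2: lookback 2020-04-01 to 2020-10-01, follow-up from 2020-10-01.
#'
#' @param followupDays outcome window length (default 180).
#' @return list of two [WaveDefinition-class] objects.
#' @export
defaultWaves <- function(followupDays = 180L) {
  list(
    waveDefinition(1L, "2019-10-01", "2020-04-01", followupDays),
    waveDefinition(2L, "2020-04-01", "2020-10-01", followupDays)
  )
}

#' Construct a drug class
#'
#' @param name class name.
#' @param bnfPrefixes character vector of BNF code prefixes.
#' @return a [DrugClass-class].
#' @export
drugClass <- function(name, bnfPrefixes) {
  methods::new("DrugClass", name = name,
               bnfPrefixes = as.character(bnfPrefixes))
}

#' Default study drug classes
#'
#' ACE inhibitors (0205051), beta blockers (0204000), calcium channel
#' blockers (0206020), thiazides (0202010) and statins (0212000B0,
#' 0212000C0, 0212000X0, 0212000Y0).
#'
#' @return named list of [DrugClass-class] objects.
#' @export
defaultDrugClasses <- function() {
  list(
    ACEI = drugClass("ACEI", "0205051"),
    BB = drugClass("BB", "0204000"),
    CCB = drugClass("CCB", "0206020"),
    THZ = drugClass("THZ", "0202010"),
    STATIN = drugClass("STATIN",
                       c("0212000B0", "0212000C0", "0212000X0", "0212000Y0"))
  )
}

#' Apply eligibility rules
#'
#' Retains patients aged >= 40 years at the index date with non-missing
#' sex, age and SIMD decile, and returns an exclusion log with counts per
#' reason. Exclusion reasons are assessed in order (age first), one reason
#' per excluded patient.
#'
#' @param demographics data.frame with patient_id, age, sex, simd_decile.
#' @param indexDate index date (unused when `age` is already age at index,
#'   as in the packaged simulator; kept for real extracts where `age` may
#'   need deriving upstream).
#' @param minAge eligibility threshold in years (default 40, inclusive).
#' @return list with `patients` (eligible rows) and `log` (data.frame of
#'   reason/n, including the retained count).
#' @export
filterEligible <- function(demographics, indexDate = as.Date("2019-10-01"),
                           minAge = 40) {
  if (is.null(demographics) || !is.data.frame(demographics))
    stop("demographics table is required")
  need <- c("patient_id", "age", "sex", "simd_decile")
  if (!all(need %in% names(demographics)))
    stop("demographics must have columns: ", paste(need, collapse = ", "))

  reason <- rep(NA_character_, nrow(demographics))
  miss <- function(x) is.na(x) | (is.character(x) & !nzchar(x))
  reason[miss(demographics$age)] <- "missing age"
  sel <- is.na(reason) & demographics$age < minAge
  reason[sel] <- sprintf("age < %s", minAge)
  sel <- is.na(reason) & miss(demographics$sex)
  reason[sel] <- "missing sex"
  sel <- is.na(reason) & miss(demographics$simd_decile)
  reason[sel] <- "missing SIMD"

  keep <- is.na(reason)
  cnt <- table(reason[!keep])
  logTab <- data.frame(reason = c(names(cnt), "eligible"),
                       n = c(as.integer(cnt), sum(keep)),
                       stringsAsFactors = FALSE)
  list(patients = demographics[keep, , drop = FALSE], log = logTab)
}

# Exposure indicators for every patient x drug over a wave's lookback
# window: 1 iff >= 1 BNF dispensing event whose code starts with one of
# the class prefixes, date in [lookbackStart, lookbackEnd).
exposureTable <- function(patientIds, events, drugs, wave) {
  inWin <- events$code_system == "BNF" &
    events$event_date >= wave@lookbackStart &
    events$event_date < wave@lookbackEnd
  ev <- events[inWin, c("patient_id", "code")]
  out <- matrix(0L, length(patientIds), length(drugs),
                dimnames = list(NULL, names(drugs)))
  for (d in seq_along(drugs)) {
    hit <- startsWithAny(ev$code, drugs[[d]]@bnfPrefixes)
    out[, d] <- as.integer(patientIds %in% unique(ev$patient_id[hit]))
  }
  out
}

#' Drug exposure of one patient in one wave
#'
#' @param patientEvents event rows of a single patient (patient_id,
#'   event_date, code, code_system).
#' @param drug a [DrugClass-class].
#' @param wave a [WaveDefinition-class].
#' @return 0/1 exposure indicator: 1 iff at least one BNF event whose code
#'   starts with a class prefix falls in `[lookbackStart, lookbackEnd)`.
#' @export
defineExposure <- function(patientEvents, drug, wave) {
  if (is.null(patientEvents) || nrow(patientEvents) == 0L) return(0L)
  hit <- patientEvents$code_system == "BNF" &
    patientEvents$event_date >= wave@lookbackStart &
    patientEvents$event_date < wave@lookbackEnd &
    startsWithAny(patientEvents$code, drug@bnfPrefixes)
  as.integer(any(hit))
}

#' Composite 180-day outcome of one patient in one wave
#'
#' The event day is the earliest of the present outcome dates (first
#' positive test, first COVID hospitalisation, COVID death) minus the
#' follow-up start, in days. `Y = 1` iff that day falls in
#' `[0, followupDays)`; otherwise `Y = 0` with administrative censoring at
#' `followupDays`. An earliest date strictly before follow-up start marks
#' the patient as prevalent (`prevalent = TRUE`), to be excluded from that
#' wave.
#'
#' @param outcomeRow one row with test_date, hosp_date, death_date
#'   (`NA` for no event).
#' @param wave a [WaveDefinition-class].
#' @return list with `Y`, `event_day`, `prevalent`.
#' @export
deriveOutcome <- function(outcomeRow, wave) {
  dts <- suppressWarnings(c(as.Date(outcomeRow$test_date),
                            as.Date(outcomeRow$hosp_date),
                            as.Date(outcomeRow$death_date)))
  dts <- dts[!is.na(dts)]
  if (length(dts) == 0L)
    return(list(Y = 0L, event_day = wave@followupDays, prevalent = FALSE))
  day <- as.numeric(min(dts) - wave@followupStart)
  if (day < 0)
    return(list(Y = 0L, event_day = wave@followupDays, prevalent = TRUE))
  if (day < wave@followupDays)
    list(Y = 1L, event_day = as.integer(day), prevalent = FALSE)
  else
    list(Y = 0L, event_day = wave@followupDays, prevalent = FALSE)
}

# Vectorised outcome derivation over an outcomes table.
deriveOutcomes <- function(outcomes, wave) {
  m <- cbind(as.numeric(as.Date(outcomes$test_date)),
             as.numeric(as.Date(outcomes$hosp_date)),
             as.numeric(as.Date(outcomes$death_date)))
  first <- suppressWarnings(apply(m, 1, min, na.rm = TRUE))
  first[!is.finite(first)] <- NA_real_
  day <- first - as.numeric(wave@followupStart)
  prevalent <- !is.na(day) & day < 0
  y <- as.integer(!is.na(day) & day >= 0 & day < wave@followupDays)
  eventDay <- ifelse(y == 1L, day, wave@followupDays)
  data.frame(patient_id = outcomes$patient_id, Y = y,
             event_day = as.integer(eventDay), prevalent = prevalent,
             stringsAsFactors = FALSE)
}

# 10-year age bands (40-49, ..., 80-89, 90+) used as undersampling strata.
ageBand <- function(age) {
  b <- pmin(floor(age / 10) * 10, 90)
  sprintf("%d-%d", b, ifelse(b >= 90, 120, b + 9))
}

#' Stratified undersampling of wave-1 negatives
#'
#' Within each (age band, sex, SIMD decile) stratum, each wave-1
#' outcome-negative patient is independently retained with probability
#' `ratio = casesWave1 / casesWave2`; all cases are retained. Excluded
#' negatives form the independent second-wave analysis pool. Deterministic
#' given `seed`.
#'
#' @param pool data.frame of wave-1 labelled patients with columns `Y`,
#'   `age`, `sex`, `simd_decile`.
#' @param casesWave1,casesWave2 case counts defining the keep ratio.
#' @param seed integer RNG seed.
#' @return list with `cohort` (retained wave-1 rows), `excluded`
#'   (negatives released to wave 2) and `ratio`.
#' @export
undersampleNegatives <- function(pool, casesWave1, casesWave2, seed = 1L) {
  ratio <- undersamplingRatio(casesWave1, casesWave2)
  if (ratio >= 1) {
    warning("undersampling ratio >= 1; retaining the full pool")
    return(list(cohort = pool, excluded = pool[0, , drop = FALSE],
                ratio = ratio))
  }
  strata <- paste(ageBand(pool$age), pool$sex, pool$simd_decile, sep = "|")
  keep <- pool$Y == 1L
  withLocalSeed(seed, {
    for (s in sort(unique(strata))) {
      idx <- which(strata == s & pool$Y == 0L)
      if (length(idx))
        keep[idx] <- stats::runif(length(idx)) < ratio
    }
  })
  list(cohort = pool[keep, , drop = FALSE],
       excluded = pool[!keep, , drop = FALSE], ratio = ratio)
}

#' Build the labelled analysis cohort
#'
#' Full study flow over raw tables: eligibility filtering; wave-1
#' exposure/outcome labelling; exclusion of wave-1 prevalent cases; with
#' two waves, stratified undersampling of wave-1 negatives at ratio
#' wave-1 cases / wave-2 cases, with excluded negatives re-labelled on the
#' wave-2 windows (exposures re-derived on the wave-2 lookback) to form the
#' second-wave cohort. Every eligible patient lands in exactly one wave.
#'
#' @param events,demographics,outcomes raw tables in the simulator's CSV
#'   schema (accepted equally for real extracts).
#' @param waves list of [WaveDefinition-class] (1 or 2 waves).
#' @param drugs named list of [DrugClass-class].
#' @param seed integer seed for the undersampling draw.
#' @param minAge eligibility age threshold.
#' @return a [LabeledCohort-class].
#' @export
buildCohort <- function(events, demographics, outcomes,
                        waves = defaultWaves(), drugs = defaultDrugClasses(),
                        seed = 1L, minAge = 40) {
  events$event_date <- as.Date(events$event_date)
  elig <- filterEligible(demographics, waves[[1]]@lookbackStart,
                         minAge = minAge)
  dg <- elig$patients
  exclusions <- elig$log
  outcomes <- outcomes[match(dg$patient_id, outcomes$patient_id), ,
                       drop = FALSE]

  labelWave <- function(ids, wave) {
    expo <- exposureTable(ids, events, drugs, wave)
    out <- deriveOutcomes(outcomes[match(ids, outcomes$patient_id), ,
                                   drop = FALSE], wave)
    df <- data.frame(patient_id = ids, wave_id = wave@waveId,
                     Y = out$Y, event_day = out$event_day,
                     prevalent = out$prevalent, stringsAsFactors = FALSE)
    cbind(df, as.data.frame(expo))
  }

  w1 <- labelWave(dg$patient_id, waves[[1]])
  nPrev <- sum(w1$prevalent)
  if (nPrev > 0) {
    exclusions <- rbind(exclusions,
                        data.frame(reason = "prevalent case (wave 1)",
                                   n = nPrev))
    w1 <- w1[!w1$prevalent, , drop = FALSE]
  }
  w1$prevalent <- NULL
  w1 <- merge(w1, dg[, c("patient_id", "age", "sex", "simd_decile",
                         "diabetes")], by = "patient_id", sort = TRUE)

  if (length(waves) == 1L) {
    labels <- w1
    ratio <- NA_real_
  } else {
    # Wave-2 case count among wave-1 negatives determines the ratio.
    w2all <- labelWave(w1$patient_id[w1$Y == 0L], waves[[2]])
    casesW1 <- sum(w1$Y == 1L)
    casesW2 <- sum(w2all$Y == 1L & !w2all$prevalent)
    us <- undersampleNegatives(w1, casesW1, casesW2, seed = seed)
    ratio <- us$ratio
    w2 <- labelWave(us$excluded$patient_id, waves[[2]])
    nPrev2 <- sum(w2$prevalent)
    if (nPrev2 > 0) {
      exclusions <- rbind(exclusions,
                          data.frame(reason = "prevalent case (wave 2)",
                                     n = nPrev2))
      w2 <- w2[!w2$prevalent, , drop = FALSE]
    }
    w2$prevalent <- NULL
    w2 <- merge(w2, dg[, c("patient_id", "age", "sex", "simd_decile",
                           "diabetes")], by = "patient_id", sort = TRUE)
    labels <- rbind(us$cohort, w2)
  }
  rownames(labels) <- NULL
  methods::new("LabeledCohort", labels = labels, exclusions = exclusions,
               undersamplingRatio = ratio, waves = waves,
               drugs = unname(drugs))
}

#' Demographic and outcome summary of a labelled cohort
#'
#' Study-style summary per wave: N, median and IQR of age, counts and
#' percentages by sex, SIMD decile and diabetes status, and outcome
#' prevalence. Returned tidy (section, level, wave_id, n, value, pct).
#'
#' @param cohort a [LabeledCohort-class] (or its labels data.frame).
#' @param topCodes optional events table; when supplied the `topK` most
#'   frequent codes per wave (by number of patients with the code in the
#'   wave lookback) are appended.
#' @param topK number of top codes to report.
#' @return data.frame summary table.
#' @export
summarizeCohort <- function(cohort, topCodes = NULL, topK = 10L) {
  labels <- if (methods::is(cohort, "LabeledCohort")) cohort@labels else cohort
  waves <- if (methods::is(cohort, "LabeledCohort")) cohort@waves else NULL
  out <- list()
  add <- function(section, level, wave, n, value = NA_real_, pct = NA_real_)
    out[[length(out) + 1L]] <<- data.frame(
      section = section, level = as.character(level), wave_id = wave,
      n = n, value = value, pct = pct, stringsAsFactors = FALSE)

  for (w in sort(unique(labels$wave_id))) {
    lw <- labels[labels$wave_id == w, , drop = FALSE]
    N <- nrow(lw)
    add("N", "total", w, N)
    q <- stats::quantile(lw$age, c(0.25, 0.5, 0.75), names = FALSE)
    add("age", "median", w, N, value = q[2])
    add("age", "iqr_low", w, N, value = q[1])
    add("age", "iqr_high", w, N, value = q[3])
    for (s in sort(unique(lw$sex)))
      add("sex", s, w, sum(lw$sex == s), pct = percentOf(sum(lw$sex == s), N))
    for (d in sort(unique(lw$simd_decile)))
      add("simd_decile", d, w, sum(lw$simd_decile == d),
          pct = percentOf(sum(lw$simd_decile == d), N))
    for (d in 0:1)
      add("diabetes", d, w, sum(lw$diabetes == d),
          pct = percentOf(sum(lw$diabetes == d), N))
    add("incident_outcome", "1", w, sum(lw$Y == 1L),
        pct = percentOf(sum(lw$Y == 1L), N))
    if (!is.null(topCodes) && !is.null(waves)) {
      wv <- Filter(function(x) x@waveId == w, waves)[[1]]
      ev <- topCodes[as.Date(topCodes$event_date) >= wv@lookbackStart &
                       as.Date(topCodes$event_date) < wv@lookbackEnd &
                       topCodes$patient_id %in% lw$patient_id, ,
                     drop = FALSE]
      cnt <- sort(table(unique(ev[, c("patient_id", "code")])$code),
                  decreasing = TRUE)
      cnt <- utils::head(cnt, topK)
      for (k in seq_along(cnt))
        add("top_code", names(cnt)[k], w, as.integer(cnt[k]),
            pct = percentOf(as.integer(cnt[k]), N))
    }
  }
  do.call(rbind, out)
}

#' @describeIn LabeledCohort labels accessor
#' @param object a `LabeledCohort`.
#' @export
setMethod("cohortLabels", "LabeledCohort", function(object) object@labels)

#' @describeIn LabeledCohort exclusion-log accessor
#' @export
setMethod("exclusionLog", "LabeledCohort", function(object)
  object@exclusions)

setMethod("show", "LabeledCohort", function(object) {
  tab <- table(object@labels$wave_id)
  cat("LabeledCohort:", nrow(object@labels), "patients (",
      paste(sprintf("wave %s: %d", names(tab), as.integer(tab)),
            collapse = ", "), ")\n")
  if (!is.na(object@undersamplingRatio))
    cat("  undersampling ratio:",
        format(object@undersamplingRatio, digits = 5), "\n")
})
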