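# Pipeline orchestration: file-based, re-entrant stages with a manifest
# recording config hash, seed and input/output checksums. A thin Rscript
# (inst/scripts/txlearner.R) exposes the same subcommands from a shell.

readCheckedCsv <- function(path, required, dateCols = character()) {
  if (!file.exists(path))
    stop("required input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(path, ": missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (cl in intersect(dateCols, names(df))) {
    vals <- df[[cl]]
    parsed <- as.Date(vals, format = "%Y-%m-%d")
    bad <- which(!is.na(vals) & nzchar(vals) & is.na(parsed))
    if (length(bad))
      stop(path, ": unparseable date in column ", cl, " at data line(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    df[[cl]] <- parsed
  }
  df
}

loadRunConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config$seed <- as.integer(config$seed %||% 1L)
  config$out_dir <- config$out_dir %||% "txlearner_out"
  config
}

writeManifest <- function(step, config, inputs, outputs) {
  tf <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE), tf)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  man <- list(
    step = step,
    seed = config$seed,
    config_hash = hash,
    package_version = as.character(utils::packageVersion("txlearner")),
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = as.list(tools::md5sum(outputs[file.exists(outputs)])))
  jsonlite::write_json(man, file.path(config$out_dir,
                                      paste0("manifest_", step, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

selectedDrugs <- function(config) {
  all <- defaultDrugClasses()
  nm <- config$drugs %||% names(all)
  all[nm]
}

runWaves <- function(config) {
  wc <- config$simulate$wave_count %||% 2L
  defaultWaves()[seq_len(wc)]
}

modelConfigFor <- function(config, seed) {
  kind <- config$causal$base_learner %||% "transformer"
  if (kind == "transformer") {
    tc <- config$causal$transformer %||% list()
    cfg <- transformerConfig(
      embedDim = tc$embed_dim %||% 64L, nHeads = tc$n_heads %||% 4L,
      nLayers = tc$n_layers %||% 2L, ffDim = tc$ff_dim %||% 128L,
      headDim = tc$head_dim %||% 32L, dropout = tc$dropout %||% 0.1,
      maxLen = tc$max_len %||% (config$causal$max_len %||% 256L),
      learningRate = tc$learning_rate %||% 1e-3,
      batchSize = tc$batch_size %||% 64L, epochs = tc$epochs %||% 30L,
      patience = tc$patience %||% 3L, seed = seed)
  } else {
    cfg <- config$causal$baseline %||% list()
    cfg$seed <- seed
  }
  list(kind = kind, cfg = cfg)
}

loadTables <- function(config) {
  dir <- config$out_dir
  ev <- config$data$events %||% file.path(dir, "events.csv")
  dm <- config$data$demographics %||% file.path(dir, "demographics.csv")
  oc <- config$data$outcomes %||% file.path(dir, "outcomes.csv")
  list(
    events = readCheckedCsv(ev, c("patient_id", "event_date", "code",
                                  "code_system"), "event_date"),
    demographics = readCheckedCsv(dm, c("patient_id", "age", "sex",
                                        "simd_decile", "diabetes")),
    outcomes = readCheckedCsv(oc, c("patient_id", "test_date", "hosp_date",
                                    "death_date"),
                              c("test_date", "hosp_date", "death_date")),
    paths = c(ev, dm, oc))
}

#' Run one pipeline stage
#'
#' Subcommands: `simulate` (synthetic tables with ground truth),
#' `build-cohort` (labelled cohort + exclusion log), `train` (fit and
#' serialise one risk model), `causal` (per-drug X-learner, `ite.csv` and
#' `ate.csv`), `evaluate` (cross-validated `metrics.csv`), `compare`
#' (paired ITE comparisons vs a reference drug), `report` (demographic
#' summary table). Every stage reads and writes only documented CSV/JSON
#' artifacts under `out_dir`, records a manifest with config hash, seed
#' and file checksums, and is deterministic given the config, so reruns
#' reproduce byte-identical outputs. Partial outputs are removed when a
#' stage fails.
#'
#' @param step subcommand name.
#' @param config named list or path to a YAML configuration.
#' @return invisibly, the paths written.
#' @export
runPipeline <- function(step = c("simulate", "build-cohort", "train",
                                 "causal", "evaluate", "compare",
                                 "report"),
                        config) {
  step <- match.arg(step)
  config <- loadRunConfig(config)
  dir <- config$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  outputs <- character()
  ok <- FALSE
  on.exit(if (!ok) unlink(outputs), add = TRUE)

  if (step == "simulate") {
    sc <- config$simulate %||% list()
    te <- sc$treatment_effects %||% list(ACEI = 0, BB = 0, CCB = 0,
                                         THZ = 0, STATIN = 0)
    cfg <- simConfig(
      nPatients = sc$n_patients %||% 5000L, seed = config$seed,
      waveCount = sc$wave_count %||% 2L,
      baseEventRate = sc$base_event_rate %||% 12,
      confoundingStrength = sc$confounding_strength %||% 1,
      treatmentEffects = te,
      outcomeBasePrevalence = sc$outcome_base_prevalence %||% 0.095,
      treatmentPrevalence = {
        tp <- c(ACEI = 0.195, BB = 0.211, CCB = 0.184, THZ = 0.06,
                STATIN = 0.25)
        tp[names(te)]
      })
    cohort <- simulateCohort(cfg, selectedDrugs(
      utils::modifyList(config, list(drugs = names(te)))))
    outputs <- writeCohortTables(cohort, dir)
    writeManifest(step, config, character(), outputs)
  } else if (step == "build-cohort") {
    tabs <- loadTables(config)
    cohort <- buildCohort(tabs$events, tabs$demographics, tabs$outcomes,
                          waves = runWaves(config),
                          drugs = selectedDrugs(config),
                          seed = config$seed,
                          minAge = config$cohort$min_age %||% 40)
    cohortPath <- file.path(dir, "cohort.csv")
    exclPath <- file.path(dir, "exclusions.log")
    outputs <- c(cohortPath, exclPath)
    utils::write.csv(cohortLabels(cohort), cohortPath, row.names = FALSE)
    writeLines(
      c(sprintf("undersampling_ratio\t%s",
                format(cohort@undersamplingRatio, digits = 10)),
        sprintf("%s\t%d", exclusionLog(cohort)$reason,
                exclusionLog(cohort)$n)),
      exclPath)
    writeManifest(step, config, tabs$paths, outputs)
  } else if (step == "train") {
    tabs <- loadTables(config)
    labels <- readCheckedCsv(file.path(dir, "cohort.csv"),
                             c("patient_id", "wave_id", "Y"))
    waveId <- config$train$wave %||% min(labels$wave_id)
    wave <- Filter(function(w) w@waveId == waveId, runWaves(config))[[1]]
    lw <- labels[labels$wave_id == waveId, , drop = FALSE]
    ms <- modelConfigFor(config, config$seed)
    maxLen <- config$causal$max_len %||% 256L
    evW <- tabs$events[tabs$events$event_date >= wave@lookbackStart &
                         tabs$events$event_date < wave@lookbackEnd &
                         tabs$events$patient_id %in% lw$patient_id, ]
    vocab <- buildVocabulary(evW)
    enc <- encodePatients(lw$patient_id, tabs$events, tabs$demographics,
                          wave, vocab, maxLen = maxLen)
    fit <- resolveBaseLearner(ms$kind, ms$cfg)(enc, lw$Y, config$seed)
    modelPath <- file.path(dir, sprintf("model_%s_wave%d.rds", ms$kind,
                                        waveId))
    logPath <- file.path(dir, "training_log.csv")
    outputs <- c(modelPath, logPath)
    saveRDS(list(model = fit, vocab = vocab), modelPath)
    lg <- if (methods::existsMethod("trainingLog", class(fit)))
      trainingLog(fit) else data.frame()
    utils::write.csv(lg, logPath, row.names = FALSE)
    writeManifest(step, config, tabs$paths, outputs)
  } else if (step == "causal") {
    tabs <- loadTables(config)
    labelsAll <- readCheckedCsv(file.path(dir, "cohort.csv"),
                                c("patient_id", "wave_id", "Y"))
    waveId <- config$causal$wave %||% min(labelsAll$wave_id)
    drugs <- selectedDrugs(config)
    waves <- runWaves(config)
    cohort <- methods::new("LabeledCohort", labels = labelsAll,
                           exclusions = data.frame(),
                           undersamplingRatio = NA_real_,
                           waves = waves, drugs = unname(drugs))
    ms <- modelConfigFor(config, config$seed)
    iteAll <- list()
    ateAll <- list()
    for (d in names(drugs)) {
      fit <- fitXLearner(cohort, drugs[[d]], tabs$events,
                         tabs$demographics, waveId = waveId,
                         baseLearner = ms$kind, baseConfig = ms$cfg,
                         maxLen = config$causal$max_len %||% 256L,
                         minArmSize = config$causal$min_arm_size %||% 50L,
                         ensembleSize = config$causal$ensemble_size %||% 1L,
                         seed = deriveSeed(config$seed, match(d,
                                                              names(drugs)),
                                           31L))
      ids <- labelsAll$patient_id[labelsAll$wave_id == waveId]
      ite <- estimateIte(fit, ids, tabs$events, tabs$demographics)
      iteAll[[d]] <- ite
      ateAll[[d]] <- estimateAte(ite)
    }
    itePath <- file.path(dir, "ite.csv")
    atePath <- file.path(dir, "ate.csv")
    outputs <- c(itePath, atePath)
    utils::write.csv(do.call(rbind, iteAll), itePath, row.names = FALSE)
    utils::write.csv(do.call(rbind, ateAll), atePath, row.names = FALSE)
    writeManifest(step, config, tabs$paths, outputs)
  } else if (step == "evaluate") {
    tabs <- loadTables(config)
    labelsAll <- readCheckedCsv(file.path(dir, "cohort.csv"),
                                c("patient_id", "wave_id", "Y"))
    waves <- runWaves(config)
    cohort <- methods::new("LabeledCohort", labels = labelsAll,
                           exclusions = data.frame(),
                           undersamplingRatio = NA_real_,
                           waves = waves, drugs = list())
    ms <- modelConfigFor(config, config$seed)
    waveIds <- config$evaluate$waves %||% sort(unique(labelsAll$wave_id))
    rows <- list()
    for (w in waveIds) {
      cv <- crossValidate(cohort, tabs$events, tabs$demographics,
                          model = config$evaluate$model %||% ms$kind,
                          config = ms$cfg, k = config$evaluate$k %||% 5L,
                          waveId = w,
                          maxLen = config$causal$max_len %||% 256L,
                          seed = config$seed)
      cv$model <- config$evaluate$model %||% ms$kind
      cv$wave <- w
      rows[[length(rows) + 1L]] <- cv[, c("model", "wave", "fold",
                                          "accuracy", "f1", "auprc")]
    }
    metricsPath <- file.path(dir, "metrics.csv")
    outputs <- metricsPath
    utils::write.csv(do.call(rbind, rows), metricsPath, row.names = FALSE)
    writeManifest(step, config, tabs$paths, outputs)
  } else if (step == "compare") {
    ite <- readCheckedCsv(file.path(dir, "ite.csv"),
                          c("patient_id", "drug", "tau_hat"))
    ref <- config$compare$reference %||% "ACEI"
    others <- setdiff(unique(ite$drug), ref)
    refIte <- ite[ite$drug == ref, , drop = FALSE]
    rows <- lapply(others, function(d) {
      oth <- ite[ite$drug == d, , drop = FALSE]
      oth <- oth[match(refIte$patient_id, oth$patient_id), , drop = FALSE]
      pairedIteComparison(refIte, oth)
    })
    cmpPath <- file.path(dir, "comparisons.csv")
    outputs <- cmpPath
    utils::write.csv(do.call(rbind, rows), cmpPath, row.names = FALSE)
    writeManifest(step, config, file.path(dir, "ite.csv"), outputs)
  } else if (step == "report") {
    tabs <- loadTables(config)
    labelsAll <- readCheckedCsv(file.path(dir, "cohort.csv"),
                                c("patient_id", "wave_id", "Y"))
    cohort <- methods::new("LabeledCohort", labels = labelsAll,
                           exclusions = data.frame(),
                           undersamplingRatio = NA_real_,
                           waves = runWaves(config), drugs = list())
    tab1 <- summarizeCohort(cohort, topCodes = tabs$events)
    t1Path <- file.path(dir, "table1.csv")
    outputs <- t1Path
    utils::write.csv(tab1, t1Path, row.names = FALSE)
    writeManifest(step, config, tabs$paths, outputs)
  }
  ok <- TRUE
  invisible(outputs)
}
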