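# Sequence encoding: truncated-code vocabulary and model-ready patient
# representations (token ids, day offsets, padding mask, static features).

truncateCodes <- function(code, codeSystem, bnfChars, icdChars) {
  n <- ifelse(codeSystem == "BNF", bnfChars, icdChars)
  substr(code, 1L, n)
}

#' Build a token vocabulary from training events
#'
#' Codes are truncated (BNF to the chemical-substance stem, ICD-10 to the
#' category) and counted over the supplied training events; codes with
#' count below `minCount` are left out and map to UNK at encoding time.
#' Token ids are assigned deterministically: descending count, ties broken
#' lexicographically, starting at 3 after the reserved PAD/UNK/CLS ids.
#' Build only from training folds to avoid test leakage.
#'
#' @param events data.frame of training events (code, code_system).
#' @param minCount minimum corpus count for a real token (default 1).
#' @param bnfChars,icdChars truncation lengths (defaults 7 and 3).
#' @return a [CodeVocabulary-class].
#' @export
buildVocabulary <- function(events, minCount = 1L, bnfChars = 7L,
                            icdChars = 3L) {
  reserved <- c(PAD = 0L, UNK = 1L, CLS = 2L)
  if (is.null(events) || nrow(events) == 0L) {
    return(methods::new("CodeVocabulary",
      tokens = data.frame(token = character(), id = integer(),
                          count = integer(), code_system = character()),
      reserved = reserved, bnfChars = as.integer(bnfChars),
      icdChars = as.integer(icdChars), minCount = as.integer(minCount)))
  }
  tok <- truncateCodes(events$code, events$code_system, bnfChars, icdChars)
  agg <- stats::aggregate(list(count = tok),
                          by = list(token = tok,
                                    code_system = events$code_system),
                          FUN = length)
  agg <- agg[agg$count >= minCount, , drop = FALSE]
  agg <- agg[order(-agg$count, agg$token), , drop = FALSE]
  agg$id <- seq_len(nrow(agg)) + 2L
  methods::new("CodeVocabulary",
    tokens = data.frame(token = agg$token, id = agg$id, count = agg$count,
                        code_system = agg$code_system,
                        stringsAsFactors = FALSE),
    reserved = reserved, bnfChars = as.integer(bnfChars),
    icdChars = as.integer(icdChars), minCount = as.integer(minCount))
}

#' Map truncated codes to token ids (UNK for unknown)
#'
#' @param vocab a [CodeVocabulary-class].
#' @param tokens character vector of already-truncated codes.
#' @return integer ids.
#' @export
tokenId <- function(vocab, tokens) {
  id <- vocab@tokens$id[match(tokens, vocab@tokens$token)]
  id[is.na(id)] <- vocab@reserved[["UNK"]]
  id
}

#' Decode token ids back to truncated codes
#'
#' @param vocab a [CodeVocabulary-class].
#' @param ids integer token ids.
#' @return character tokens ("<PAD>", "<UNK>", "<CLS>" for reserved ids).
#' @export
decodeTokens <- function(vocab, ids) {
  out <- vocab@tokens$token[match(ids, vocab@tokens$id)]
  res <- c("<PAD>", "<UNK>", "<CLS>")
  out[ids %in% 0:2] <- res[ids[ids %in% 0:2] + 1L]
  out
}

#' Age-standardisation statistics from training demographics
#'
#' @param demographics training demographics data.frame.
#' @return list with `ageMean`, `ageSd`.
#' @export
staticScaler <- function(demographics) {
  s <- stats::sd(demographics$age)
  list(ageMean = mean(demographics$age),
       ageSd = if (is.na(s) || s == 0) 1 else s)
}

#' Encode patients for the sequence models
#'
#' For each requested patient, selects lookback-window events, optionally
#' removes events whose raw code starts with one of `excludePrefixes` (the
#' leakage guard for the index drug's own dispenses), sorts by (date, BNF
#' before ICD-10, code), keeps the `maxLen` most recent, and maps truncated
#' codes to token ids with day offsets measured from the lookback start.
#' Patients with no retained events get an all-PAD row with valid static
#' features. Deterministic throughout.
#'
#' @param patientIds character vector defining row order of the output.
#' @param events events table (patient_id, event_date, code, code_system).
#' @param demographics demographics covering `patientIds`.
#' @param wave a [WaveDefinition-class] supplying the lookback window.
#' @param vocab a [CodeVocabulary-class] built on training data.
#' @param maxLen sequence capacity (default 256); longest-ago events are
#'   dropped first.
#' @param excludePrefixes character vector of raw-code prefixes to remove
#'   before encoding (default none).
#' @param scaler list from [staticScaler()]; defaults to statistics of
#'   `demographics` (supply the training-fold scaler when encoding test
#'   folds).
#' @return an [EncodedCohort-class].
#' @export
encodePatients <- function(patientIds, events, demographics, wave, vocab,
                           maxLen = 256L, excludePrefixes = character(),
                           scaler = NULL) {
  maxLen <- as.integer(maxLen)
  if (is.null(scaler)) scaler <- staticScaler(demographics)
  lookbackDays <- as.integer(wave@lookbackEnd - wave@lookbackStart)

  ev <- events
  ev$event_date <- as.Date(ev$event_date)
  ev <- ev[ev$patient_id %in% patientIds &
             ev$event_date >= wave@lookbackStart &
             ev$event_date < wave@lookbackEnd, , drop = FALSE]
  if (length(excludePrefixes))
    ev <- ev[!startsWithAny(ev$code, excludePrefixes), , drop = FALSE]
  # BNF sorts before ICD10 alphabetically, giving the required tie-break.
  ev <- ev[order(ev$patient_id, ev$event_date, ev$code_system, ev$code), ,
           drop = FALSE]

  n <- length(patientIds)
  tokM <- matrix(0L, n, maxLen)
  dayM <- matrix(0L, n, maxLen)
  if (nrow(ev)) {
    ev$token <- tokenId(vocab, truncateCodes(ev$code, ev$code_system,
                                             vocab@bnfChars,
                                             vocab@icdChars))
    ev$day <- as.integer(ev$event_date - wave@lookbackStart)
    split_tok <- split(ev$token, ev$patient_id)
    split_day <- split(ev$day, ev$patient_id)
    rows <- match(names(split_tok), patientIds)
    for (j in seq_along(split_tok)) {
      tk <- split_tok[[j]]
      dy <- split_day[[j]]
      if (length(tk) > maxLen) {  # keep the most recent events
        keep <- seq.int(length(tk) - maxLen + 1L, length(tk))
        tk <- tk[keep]; dy <- dy[keep]
      }
      tokM[rows[j], seq_along(tk)] <- tk
      dayM[rows[j], seq_along(dy)] <- dy
    }
  }
  dm <- demographics[match(patientIds, demographics$patient_id), ,
                     drop = FALSE]
  statics <- cbind(
    age_z = (dm$age - scaler$ageMean) / scaler$ageSd,
    male = as.numeric(dm$sex == "M"),
    simd = as.numeric(dm$simd_decile),
    diabetes = as.numeric(dm$diabetes))

  methods::new("EncodedCohort",
    patientId = as.character(patientIds), tokenIds = tokM,
    dayOffsets = dayM, paddingMask = tokM == 0L,
    staticFeatures = statics, maxLen = maxLen,
    lookbackDays = lookbackDays, vocab = vocab, scaler = scaler)
}

#' Bag-of-token count features plus statics
#'
#' Collapses each encoded sequence to per-token counts (one column per
#' vocabulary entry incl. UNK) appended to the static features; the
#' representation used by the logistic and boosted-trees baselines and the
#' stage-3/propensity models' token summaries.
#'
#' @param encoded an [EncodedCohort-class].
#' @param level `"tokens"` for full per-token counts, `"systems"` for
#'   `log1p` total counts per code system only.
#' @return numeric matrix with named columns.
#' @export
featureMatrix <- function(encoded, level = c("tokens", "systems")) {
  level <- match.arg(level)
  tok <- encoded@tokenIds
  n <- nrow(tok)
  vt <- encoded@vocab@tokens
  if (level == "tokens") {
    ids <- c(1L, vt$id)  # UNK first, then real tokens
    cnt <- matrix(0, n, length(ids),
                  dimnames = list(NULL, c("UNK", vt$token)))
    for (j in seq_along(ids))
      cnt[, j] <- rowSums(tok == ids[j])
  } else {
    isBnf <- vt$id[vt$code_system == "BNF"]
    isIcd <- vt$id[vt$code_system == "ICD10"]
    cnt <- cbind(
      log_bnf = log1p(rowSums(matrix(tok %in% isBnf, n))),
      log_icd = log1p(rowSums(matrix(tok %in% isIcd, n))),
      log_unk = log1p(rowSums(tok == 1L)))
  }
  cbind(encoded@staticFeatures, cnt)
}

#' Serialise a vocabulary to JSON
#'
#' Deterministic serialisation (token, id, count, code_system) plus the
#' truncation settings.
#'
#' @param vocab a [CodeVocabulary-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeVocabulary <- function(vocab, path) {
  obj <- list(bnf_chars = vocab@bnfChars, icd_chars = vocab@icdChars,
              min_count = vocab@minCount,
              reserved = as.list(vocab@reserved),
              tokens = vocab@tokens)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @describeIn CodeVocabulary token table accessor
#' @param object a `CodeVocabulary`.
#' @export
setMethod("vocabTokens", "CodeVocabulary", function(object) object@tokens)

#' @describeIn CodeVocabulary total number of token ids (reserved + real)
#' @export
setMethod("vocabSize", "CodeVocabulary", function(object)
  nrow(object@tokens) + 3L)

setMethod("show", "CodeVocabulary", function(object) {
  cat("CodeVocabulary:", nrow(object@tokens), "tokens (+3 reserved),",
      "BNF", object@bnfChars, "chars / ICD-10", object@icdChars, "chars\n")
})

#' @describeIn EncodedCohort token id matrix accessor
#' @param object an `EncodedCohort`.
#' @export
setMethod("tokenIds", "EncodedCohort", function(object) object@tokenIds)

#' @describeIn EncodedCohort day offset matrix accessor
#' @export
setMethod("dayOffsets", "EncodedCohort", function(object)
  object@dayOffsets)

#' @describeIn EncodedCohort padding mask accessor (TRUE = PAD)
#' @export
setMethod("paddingMask", "EncodedCohort", function(object)
  object@paddingMask)

#' @describeIn EncodedCohort static feature matrix accessor
#' @export
setMethod("staticFeatures", "EncodedCohort", function(object)
  object@staticFeatures)

#' @describeIn EncodedCohort patient id accessor
#' @export
setMethod("patientIds", "EncodedCohort", function(object) object@patientId)

setMethod("show", "EncodedCohort", function(object) {
  cat("EncodedCohort:", nrow(object@tokenIds), "patients, maxLen",
      object@maxLen, ", vocab", vocabSize(object@vocab), "ids\n")
})
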