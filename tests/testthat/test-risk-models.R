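# The neural models' backward passes are checked against central finite
# differences at a tiny size, then the training contracts (capacity,
# determinism, masking, probability bounds) at small scale.

gradCase <- function() {
  withr::with_seed(3, {
    n <- 6
    tokens <- lapply(1:n, function(i)
      if (i == 5) integer(0) else sample(1:9, sample(2:7, 1),
                                         replace = TRUE))
    buckets <- lapply(tokens, function(t)
      if (!length(t)) integer(0) else sort(sample(0:17, length(t),
                                                  replace = TRUE)))
    list(tokens = tokens, buckets = buckets,
         statics = matrix(rnorm(n * 4), n, 4), y = c(1, 0, 1, 0, 1, 0))
  })
}

test_that("transformer gradients match finite differences", {
  cs <- gradCase()
  dims <- list(vocab_size = 10L, max_len = 8L, embed_dim = 8L,
               n_heads = 2L, n_layers = 2L, ff_dim = 12L, n_buckets = 18L,
               head_dim = 6L)
  params <- c("Etok", "Epos", "Etime", "Wq1", "Wk2", "Wv1", "Wo2", "W11",
              "W22", "b11", "g11", "be22", "Wh1", "Wh2", "bh1", "bq1",
              "bo2")
  for (pn in params) {
    r <- txlearner:::cpp_transformer_gradcheck(
      cs$tokens, cs$buckets, cs$statics, cs$y, dims, 42L, pn, 0L, 1e-5)
    expect_lt(abs(r$analytic - r$numeric),
              1e-4 * max(1, abs(r$numeric)))
  }
})

test_that("LSTM gradients match finite differences", {
  cs <- gradCase()
  dims <- list(vocab_size = 10L, embed_dim = 8L, hidden_dim = 7L,
               n_buckets = 18L, head_dim = 6L)
  for (pn in c("Etok", "Etime", "Wx", "Wh", "b", "Wh1", "bh1", "Wh2")) {
    r <- txlearner:::cpp_lstm_gradcheck(
      cs$tokens, cs$buckets, cs$statics, cs$y, dims, 42L, pn, 0L, 1e-5)
    expect_lt(abs(r$analytic - r$numeric),
              1e-4 * max(1, abs(r$numeric)))
  }
})

separableSet <- function() {
  w <- smallWorld()
  vocab <- buildVocabulary(w$events)
  enc <- encodePatients(w$labels$patient_id[1:200], w$events,
                        w$demographics, w$wave, vocab, maxLen = 32L)
  vt <- vocabTokens(vocab)
  marker <- vt$id[vt$token == "0403030"]  # SSRI dispense marks the class
  y <- as.integer(apply(tokenIds(enc), 1, function(r) any(r == marker)))
  list(enc = enc, y = y)
}

test_that("the transformer can separate a token-defined outcome", {
  s <- separableSet()
  cfg <- transformerConfig(embedDim = 16L, nHeads = 2L, nLayers = 2L,
                           ffDim = 32L, maxLen = 32L, epochs = 50L,
                           patience = 50L, batchSize = 32L, seed = 2)
  fit <- trainTransformer(s$enc, s$y, cfg)
  expect_gte(mean((predictRisk(fit, s$enc) >= 0.5) == s$y), 0.95)
})

test_that("boosted trees separate the same outcome", {
  s <- separableSet()
  fit <- trainBaseline(s$enc, s$y, "boosted_trees",
                       list(nrounds = 60L, seed = 2))
  expect_gte(mean((predictRisk(fit, s$enc) >= 0.5) == s$y), 0.95)
})

test_that("the LSTM learns and satisfies the probability contract", {
  s <- separableSet()
  fit <- trainBaseline(s$enc, s$y, "lstm",
                       list(epochs = 40L, patience = 40L, batchSize = 32L,
                            seed = 2))
  p <- predictRisk(fit, s$enc)
  expect_true(all(is.finite(p) & p >= 0 & p <= 1))
  expect_gte(mean((p >= 0.5) == s$y), 0.90)
})

test_that("training is deterministic for a fixed seed", {
  s <- separableSet()
  cfg <- transformerConfig(embedDim = 16L, nHeads = 2L, nLayers = 1L,
                           ffDim = 32L, maxLen = 32L, epochs = 4L,
                           batchSize = 64L, seed = 9)
  f1 <- trainTransformer(s$enc, s$y, cfg)
  f2 <- trainTransformer(s$enc, s$y, cfg)
  expect_identical(trainingLog(f1), trainingLog(f2))
  expect_identical(predictRisk(f1, s$enc), predictRisk(f2, s$enc))
})

test_that("patients without events are scored from statics alone", {
  ev <- makeEvents("X001", "2020-01-01", "0103050AA")
  dm <- makeDemographics(4, age = c(50, 50, 80, 80), sex = "F")
  vocab <- buildVocabulary(ev)
  enc <- encodePatients(dm$patient_id, ev[0, ], dm,
                        defaultWaves()[[1]], vocab, maxLen = 6L)
  cfg <- transformerConfig(embedDim = 8L, nHeads = 2L, nLayers = 1L,
                           ffDim = 16L, maxLen = 6L, epochs = 2L,
                           batchSize = 2L, valFraction = 0.3, seed = 1)
  fit <- trainTransformer(enc, c(1, 0, 1, 0), cfg)
  p <- predictRisk(fit, enc)
  expect_equal(p[1], p[2])  # identical statics, no events
  expect_equal(p[3], p[4])
})

test_that("padding capacity never changes predictions", {
  s <- separableSet()
  cfg <- transformerConfig(embedDim = 16L, nHeads = 2L, nLayers = 1L,
                           ffDim = 32L, maxLen = 32L, epochs = 2L,
                           batchSize = 64L, seed = 3)
  fit <- trainTransformer(s$enc, s$y, cfg)
  w <- smallWorld()
  ids <- w$labels$patient_id[1:40]
  encNarrow <- encodePatients(ids, w$events, w$demographics, w$wave,
                              s$enc@vocab, maxLen = 24L)
  encWide <- encodePatients(ids, w$events, w$demographics, w$wave,
                            s$enc@vocab, maxLen = 32L)
  short <- rowSums(tokenIds(encWide) != 0L) <= 24L
  expect_true(any(short))
  expect_equal(predictRisk(fit, encNarrow)[short],
               predictRisk(fit, encWide)[short], tolerance = 1e-6)
})

test_that("logistic baseline recovers a well-specified model", {
  withr::with_seed(5, {
    n <- 10000
    dm <- data.frame(patient_id = sprintf("L%05d", 1:n),
                     age = stats::rnorm(n, 60, 10),
                     sex = sample(c("F", "M"), n, replace = TRUE),
                     simd_decile = sample(1:10, n, replace = TRUE),
                     diabetes = stats::rbinom(n, 1, 0.2),
                     stringsAsFactors = FALSE)
    vocab <- buildVocabulary(makeEvents("x", "2020-01-01", "0103050AA"))
    enc <- encodePatients(dm$patient_id, makeEvents("x", "2020-01-01",
                                                    "0103050AA")[0, ],
                          dm, defaultWaves()[[1]], vocab, maxLen = 4L)
    X <- staticFeatures(enc)
    beta <- c(age_z = 0.8, male = -0.5, simd = 0.15, diabetes = 0.7)
    y <- stats::rbinom(n, 1, stats::plogis(-1 + X %*% beta))
    fit <- trainBaseline(enc, y, "logistic")
    est <- fit@coef[names(beta)]
    expect_true(all(abs(est - beta) / abs(beta) < 0.2))
  })
})

test_that("a constant-feature cohort is scored at the prevalence", {
  dm <- makeDemographics(400)
  vocab <- buildVocabulary(makeEvents("x", "2020-01-01", "0103050AA"))
  enc <- encodePatients(dm$patient_id,
                        makeEvents("x", "2020-01-01", "0103050AA")[0, ],
                        dm, defaultWaves()[[1]], vocab, maxLen = 4L)
  y <- rep(c(1L, 0L), c(120, 280))
  fit <- trainBaseline(enc, y, "logistic")
  expect_lt(max(abs(predictRisk(fit, enc) - 0.3)), 0.01)
})

test_that("prediction is order-equivariant and rejects bad input", {
  s <- separableSet()
  cfg <- transformerConfig(embedDim = 8L, nHeads = 2L, nLayers = 1L,
                           ffDim = 16L, maxLen = 32L, epochs = 1L,
                           batchSize = 64L, seed = 4)
  fit <- trainTransformer(s$enc, s$y, cfg)
  p <- predictRisk(fit, s$enc)
  expect_true(all(is.finite(p) & p >= 0 & p <= 1))
  perm <- rev(seq_along(p))
  encPerm <- txlearner:::encodedSubset(s$enc, perm)
  expect_identical(predictRisk(fit, encPerm), p[perm])
  dup <- txlearner:::encodedSubset(s$enc, c(1, 1))
  pd <- predictRisk(fit, dup)
  expect_identical(pd[1], pd[2])
  empty <- txlearner:::encodedSubset(s$enc, integer(0))
  expect_identical(predictRisk(fit, empty), numeric(0))
  # vocabulary mismatch
  w <- smallWorld()
  vSmall <- buildVocabulary(w$events[1:20, ])
  encBad <- encodePatients(w$labels$patient_id[1:5], w$events,
                           w$demographics, w$wave, vSmall, maxLen = 32L)
  expect_error(predictRisk(fit, encBad), "vocabulary mismatch")
  expect_error(trainTransformer(s$enc, rep(1L, length(s$y)),
                                transformerConfig(seed = 1)),
               "single class")
})
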