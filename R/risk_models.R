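# Outcome risk models: transformer (primary) and the logistic /
# boosted-trees / LSTM comparison baselines, all satisfying the same
# predictRisk() contract.

#' Transformer hyperparameter constructor
#'
#' Defaults are sized for desk-scale training on undersampled cohorts.
#'
#' @param embedDim embedding width (divisible by `nHeads`).
#' @param nHeads,nLayers attention heads and encoder layers.
#' @param ffDim feed-forward sublayer width.
#' @param headDim classification-head hidden width.
#' @param dropout dropout rate.
#' @param maxLen sequence capacity.
#' @param learningRate,batchSize,epochs,patience Adam schedule with early
#'   stopping.
#' @param valFraction fraction (stratified by outcome) held out for early
#'   stopping.
#' @param timeBucketDays width of the learned time-embedding buckets.
#' @param seed integer seed for initialisation, shuffling and dropout.
#' @return a [TransformerConfig-class].
#' @export
transformerConfig <- function(embedDim = 64L, nHeads = 4L, nLayers = 2L,
                              ffDim = 128L, headDim = 32L, dropout = 0.1,
                              maxLen = 256L, learningRate = 1e-3,
                              batchSize = 64L, epochs = 30L, patience = 3L,
                              valFraction = 0.1, timeBucketDays = 10L,
                              seed = 1L) {
  methods::new("TransformerConfig",
    embedDim = as.integer(embedDim), nHeads = as.integer(nHeads),
    nLayers = as.integer(nLayers), ffDim = as.integer(ffDim),
    headDim = as.integer(headDim), dropout = dropout,
    maxLen = as.integer(maxLen), learningRate = learningRate,
    batchSize = as.integer(batchSize), epochs = as.integer(epochs),
    patience = as.integer(patience), valFraction = valFraction,
    timeBucketDays = as.integer(timeBucketDays), seed = as.integer(seed))
}

# Variable-length token/bucket lists (padding stripped) for the C++ models.
seqInputs <- function(encoded, bucketDays) {
  nBuckets <- max(1L, as.integer(ceiling(encoded@lookbackDays / bucketDays)))
  tok <- encoded@tokenIds
  day <- encoded@dayOffsets
  n <- nrow(tok)
  tokens <- vector("list", n)
  buckets <- vector("list", n)
  for (i in seq_len(n)) {
    real <- which(tok[i, ] != 0L)
    tokens[[i]] <- as.integer(tok[i, real])
    buckets[[i]] <- pmin(day[i, real] %/% bucketDays, nBuckets - 1L)
  }
  list(tokens = tokens, buckets = buckets, nBuckets = nBuckets)
}

# Stratified-by-outcome validation split (indices are 0-based for C++).
valSplit <- function(y, valFraction, seed) {
  idx <- seq_along(y)
  val <- withLocalSeed(seed, {
    unlist(lapply(split(idx, y), function(g) {
      k <- max(1L, round(length(g) * valFraction))
      sample(g, k)
    }))
  })
  list(train = setdiff(idx, val) - 1L, val = sort(val) - 1L)
}

checkTrainable <- function(y) {
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class; cannot fit a classifier")
}

#' Train the transformer risk model
#'
#' Architecture: token + positional + time-bucket embeddings, a stack of
#' post-norm multi-head self-attention encoder layers over the real (non-PAD)
#' events, masked mean pooling, concatenation of static covariates, a
#' two-layer feed-forward head and a logistic output, trained by Adam on
#' binary cross-entropy with early stopping on a stratified validation
#' split. Deterministic for fixed seed, data and config.
#'
#' @param encoded an [EncodedCohort-class].
#' @param y binary outcome labels aligned with `encoded`.
#' @param config a [TransformerConfig-class].
#' @return a [TransformerModel-class].
#' @export
trainTransformer <- function(encoded, y, config = transformerConfig()) {
  methods::validObject(config)
  checkTrainable(y)
  sq <- seqInputs(encoded, config@timeBucketDays)
  sp <- valSplit(y, config@valFraction, config@seed)
  dims <- list(vocab_size = vocabSize(encoded@vocab),
               max_len = encoded@maxLen, embed_dim = config@embedDim,
               n_heads = config@nHeads, n_layers = config@nLayers,
               ff_dim = config@ffDim, n_buckets = sq$nBuckets,
               head_dim = config@headDim)
  hyper <- list(learning_rate = config@learningRate,
                dropout = config@dropout, batch_size = config@batchSize,
                epochs = config@epochs, patience = config@patience)
  fit <- cpp_transformer_train(sq$tokens, sq$buckets,
                               encoded@staticFeatures, as.numeric(y),
                               as.integer(sp$train), as.integer(sp$val),
                               dims, hyper, config@seed)
  if (isTRUE(fit$nan))
    stop("transformer training diverged (non-finite loss)")
  methods::new("TransformerModel", weights = fit$weights, config = config,
               log = data.frame(epoch = seq_along(fit$train_loss),
                                train_loss = fit$train_loss,
                                val_loss = fit$val_loss),
               vocabSize = dims$vocab_size,
               nBuckets = as.integer(sq$nBuckets),
               staticDim = ncol(encoded@staticFeatures))
}

checkVocabMatch <- function(model, encoded) {
  if (vocabSize(encoded@vocab) != model@vocabSize)
    stop("vocabulary mismatch: encode patients with the training vocabulary")
}

#' @describeIn predictRisk transformer forward pass (no dropout)
#' @export
setMethod("predictRisk", "TransformerModel", function(object, encoded, ...) {
  checkVocabMatch(object, encoded)
  if (nrow(encoded@tokenIds) == 0L) return(numeric(0))
  maxReal <- max(rowSums(encoded@tokenIds != 0L))
  if (maxReal > nrow(object@weights$Epos))
    stop("sequence longer than the trained positional capacity; ",
         "re-encode with maxLen <= ", nrow(object@weights$Epos))
  sq <- seqInputs(encoded, object@config@timeBucketDays)
  dims <- list(vocab_size = object@vocabSize, max_len = encoded@maxLen,
               embed_dim = object@config@embedDim,
               n_heads = object@config@nHeads,
               n_layers = object@config@nLayers,
               ff_dim = object@config@ffDim, n_buckets = object@nBuckets,
               head_dim = object@config@headDim)
  as.numeric(cpp_transformer_predict(object@weights, dims, sq$tokens,
                                     sq$buckets, encoded@staticFeatures))
})

#' Train a comparison baseline
#'
#' `logistic` and `boosted_trees` operate on bag-of-token counts plus
#' static features; `lstm` consumes the same encoded sequences as the
#' transformer (last-hidden-state readout, static fusion, identical head).
#'
#' @param encoded an [EncodedCohort-class].
#' @param y binary outcome labels.
#' @param kind one of "logistic", "boosted_trees", "lstm".
#' @param config named list of hyperparameters overriding the defaults
#'   (trees: nrounds 150, eta 0.1, maxDepth 4; lstm: embedDim 32,
#'   hiddenDim 32, headDim 32, dropout 0.1, learningRate 1e-3, batchSize
#'   64, epochs 30, patience 3, valFraction 0.1, timeBucketDays 10;
#'   all: seed 1).
#' @return a fitted [RiskModel-class].
#' @export
trainBaseline <- function(encoded, y,
                          kind = c("logistic", "boosted_trees", "lstm"),
                          config = list()) {
  kind <- match.arg(kind)
  checkTrainable(y)
  seed <- config$seed %||% 1L
  if (kind == "logistic") {
    X <- featureMatrix(encoded, "tokens")
    fit <- suppressWarnings(
      stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                     family = stats::binomial()))
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    methods::new("LogisticRiskModel", coef = cf,
                 featureNames = colnames(X))
  } else if (kind == "boosted_trees") {
    X <- featureMatrix(encoded, "tokens")
    params <- list(objective = "binary:logistic",
                   eta = config$eta %||% 0.1,
                   max_depth = config$maxDepth %||% 4L,
                   nthread = 1L, seed = seed)
    bst <- xgboost::xgb.train(params = params,
                              data = xgboost::xgb.DMatrix(X, label = y),
                              nrounds = config$nrounds %||% 150L,
                              verbose = 0)
    methods::new("BoostedTreesModel", booster = bst,
                 featureNames = colnames(X))
  } else {
    bucketDays <- config$timeBucketDays %||% 10L
    sq <- seqInputs(encoded, bucketDays)
    sp <- valSplit(y, config$valFraction %||% 0.1, seed)
    dims <- list(vocab_size = vocabSize(encoded@vocab),
                 embed_dim = config$embedDim %||% 32L,
                 hidden_dim = config$hiddenDim %||% 32L,
                 n_buckets = sq$nBuckets,
                 head_dim = config$headDim %||% 32L)
    hyper <- list(learning_rate = config$learningRate %||% 1e-3,
                  dropout = config$dropout %||% 0.1,
                  batch_size = config$batchSize %||% 64L,
                  epochs = config$epochs %||% 30L,
                  patience = config$patience %||% 3L)
    fit <- cpp_lstm_train(sq$tokens, sq$buckets, encoded@staticFeatures,
                          as.numeric(y), as.integer(sp$train),
                          as.integer(sp$val), dims, hyper,
                          as.integer(seed))
    if (isTRUE(fit$nan)) stop("LSTM training diverged (non-finite loss)")
    cfg <- utils::modifyList(
      list(embedDim = 32L, hiddenDim = 32L, headDim = 32L, dropout = 0.1,
           learningRate = 1e-3, batchSize = 64L, epochs = 30L,
           patience = 3L, valFraction = 0.1, timeBucketDays = 10L,
           seed = seed), config)
    methods::new("LSTMModel", weights = fit$weights, config = cfg,
                 log = data.frame(epoch = seq_along(fit$train_loss),
                                  train_loss = fit$train_loss,
                                  val_loss = fit$val_loss),
                 vocabSize = dims$vocab_size,
                 nBuckets = as.integer(sq$nBuckets),
                 staticDim = ncol(encoded@staticFeatures))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn predictRisk logistic regression on bag-of-token features
#' @export
setMethod("predictRisk", "LogisticRiskModel", function(object, encoded, ...) {
  X <- featureMatrix(encoded, "tokens")
  if (!identical(colnames(X), object@featureNames))
    stop("vocabulary mismatch: encode patients with the training vocabulary")
  if (nrow(X) == 0L) return(numeric(0))
  as.numeric(stats::plogis(cbind(1, X) %*% object@coef))
})

#' @describeIn predictRisk gradient-boosted trees on bag-of-token features
#' @export
setMethod("predictRisk", "BoostedTreesModel", function(object, encoded, ...) {
  X <- featureMatrix(encoded, "tokens")
  if (!identical(colnames(X), object@featureNames))
    stop("vocabulary mismatch: encode patients with the training vocabulary")
  if (nrow(X) == 0L) return(numeric(0))
  as.numeric(stats::predict(object@booster, xgboost::xgb.DMatrix(X)))
})

#' @describeIn predictRisk LSTM forward pass (no dropout)
#' @export
setMethod("predictRisk", "LSTMModel", function(object, encoded, ...) {
  checkVocabMatch(object, encoded)
  if (nrow(encoded@tokenIds) == 0L) return(numeric(0))
  sq <- seqInputs(encoded, object@config$timeBucketDays %||% 10L)
  dims <- list(vocab_size = object@vocabSize,
               embed_dim = object@config$embedDim %||% 32L,
               hidden_dim = object@config$hiddenDim %||% 32L,
               n_buckets = object@nBuckets,
               head_dim = object@config$headDim %||% 32L)
  as.numeric(cpp_lstm_predict(object@weights, dims, sq$tokens, sq$buckets,
                              encoded@staticFeatures))
})

#' Wrap a prediction function as a risk model
#'
#' @param fn function taking an [EncodedCohort-class] and returning one
#'   probability per patient.
#' @return a [FunctionRiskModel-class].
#' @export
functionRiskModel <- function(fn) methods::new("FunctionRiskModel", fn = fn)

#' @describeIn predictRisk arbitrary prediction function
#' @export
setMethod("predictRisk", "FunctionRiskModel", function(object, encoded, ...) {
  p <- object@fn(encoded)
  stopifnot(length(p) == nrow(encoded@tokenIds), all(is.finite(p)))
  pmin(1, pmax(0, as.numeric(p)))
})

#' @describeIn TransformerModel training-log accessor
#' @param object a fitted model.
#' @export
setMethod("trainingLog", "TransformerModel", function(object) object@log)

#' @describeIn LSTMModel training-log accessor
#' @export
setMethod("trainingLog", "LSTMModel", function(object) object@log)

setMethod("show", "TransformerModel", function(object) {
  cat("TransformerModel: d =", object@config@embedDim, ", heads =",
      object@config@nHeads, ", layers =", object@config@nLayers,
      ",", nrow(object@log), "epochs trained\n")
})
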