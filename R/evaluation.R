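# Evaluation: cross-validated classification metrics for imbalanced
# outcomes, paired signed-rank comparisons of ITE distributions with
# effect sizes, subgroup consistency summaries, and ground-truth recovery
# diagnostics for simulated cohorts.

#' Area under the precision-recall curve
#'
#' The PR curve is evaluated at every distinct score threshold (predicting
#' positive at score >= threshold); the area is the trapezoidal integral
#' over recall, anchored at recall 0 with the precision of the first
#' (highest-score) threshold. A constant score therefore yields the
#' outcome prevalence, the no-skill baseline.
#'
#' @param y binary labels.
#' @param scores numeric scores (higher = more positive).
#' @return AUPRC in `[0, 1]` (NA when `y` has no positives).
#' @export
auprc <- function(y, scores) {
  stopifnot(length(y) == length(scores))
  nPos <- sum(y == 1)
  if (nPos == 0L) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]
  ss <- scores[o]
  tp <- cumsum(ys == 1)
  fp <- cumsum(ys != 1)
  keep <- c(diff(ss) != 0, TRUE)  # last index of each tied-score block
  tp <- tp[keep]
  fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / nPos
  recPrev <- c(0, rec[-length(rec)])
  precPrev <- c(prec[1], prec[-length(prec)])
  sum((rec - recPrev) * (prec + precPrev) / 2)
}

#' Threshold classification metrics
#'
#' @param y binary labels.
#' @param scores predicted probabilities.
#' @param threshold classification cut-point for accuracy/F1 (default 0.5).
#' @return named vector (accuracy, f1, auprc).
#' @export
classificationMetrics <- function(y, scores, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  c(accuracy = mean(pred == y), f1 = f1, auprc = auprc(y, scores))
}

# Stratified-by-outcome fold assignment; redraws when a fold would be
# single-class, errors after maxAttempts.
stratifiedFolds <- function(y, k, seed, maxAttempts = 5L) {
  for (a in seq_len(maxAttempts)) {
    folds <- withLocalSeed(deriveSeed(seed, a, 21L), {
      f <- integer(length(y))
      for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        f[idx] <- rep_len(seq_len(k), length(idx))
      }
      f
    })
    ok <- all(vapply(seq_len(k), function(j)
      length(unique(y[folds == j])) == 2L, TRUE))
    if (ok) return(folds)
    warning("single-class fold drawn; redrawing folds")
  }
  stop("could not draw ", k, "-fold split without a single-class fold")
}

#' Cross-validated predictive evaluation
#'
#' Stratified k-fold cross-validation of a risk model on one wave of a
#' labelled cohort. The vocabulary and the age scaler are rebuilt on each
#' training fold only; accuracy and F1 use the fixed threshold, AUPRC the
#' full score distribution.
#'
#' @param cohort a [LabeledCohort-class].
#' @param events,demographics raw tables covering the cohort.
#' @param model `"transformer"`, `"logistic"`, `"boosted_trees"`,
#'   `"lstm"`, or a factory `function(encoded, y, seed)` returning a
#'   [RiskModel-class].
#' @param config model configuration (see [fitXLearner()]'s `baseConfig`).
#' @param k number of folds (default 5).
#' @param waveId wave to evaluate (default: first present).
#' @param maxLen sequence capacity.
#' @param threshold classification threshold (default 0.5).
#' @param vocabMinCount vocabulary minimum count.
#' @param seed integer seed (folds and model fits).
#' @return data.frame of per-fold metrics with a `summary` attribute
#'   holding mean and SD per metric.
#' @export
crossValidate <- function(cohort, events, demographics,
                          model = "transformer", config = NULL, k = 5L,
                          waveId = NULL, maxLen = 256L, threshold = 0.5,
                          vocabMinCount = 1L, seed = 1L) {
  stopifnot(k >= 2L)
  labels <- cohortLabels(cohort)
  if (is.null(waveId)) waveId <- min(labels$wave_id)
  wave <- Filter(function(w) w@waveId == waveId, cohort@waves)[[1]]
  labels <- labels[labels$wave_id == waveId, , drop = FALSE]
  y <- labels$Y
  folds <- stratifiedFolds(y, k, seed)
  factory <- resolveBaseLearner(model, config)
  events$event_date <- as.Date(events$event_date)

  res <- lapply(seq_len(k), function(j) {
    trIds <- labels$patient_id[folds != j]
    teIds <- labels$patient_id[folds == j]
    evTr <- events[events$patient_id %in% trIds &
                     events$event_date >= wave@lookbackStart &
                     events$event_date < wave@lookbackEnd, , drop = FALSE]
    vocab <- buildVocabulary(evTr, minCount = vocabMinCount)
    scaler <- staticScaler(
      demographics[demographics$patient_id %in% trIds, , drop = FALSE])
    encTr <- encodePatients(trIds, events, demographics, wave, vocab,
                            maxLen = maxLen, scaler = scaler)
    encTe <- encodePatients(teIds, events, demographics, wave, vocab,
                            maxLen = maxLen, scaler = scaler)
    fit <- factory(encTr, y[folds != j], deriveSeed(seed, j, 22L))
    m <- classificationMetrics(y[folds == j], predictRisk(fit, encTe),
                               threshold)
    data.frame(fold = j, accuracy = m[["accuracy"]], f1 = m[["f1"]],
               auprc = m[["auprc"]])
  })
  out <- do.call(rbind, res)
  attr(out, "summary") <- data.frame(
    metric = c("accuracy", "f1", "auprc"),
    mean = c(mean(out$accuracy), mean(out$f1), mean(out$auprc)),
    sd = c(stats::sd(out$accuracy), stats::sd(out$f1),
           stats::sd(out$auprc)))
  out
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; absolute differences are mid-ranked; the
#' test statistic V is the sum of positive-difference ranks. The reported
#' Z uses the tie-corrected normal approximation with continuity
#' correction; the p-value is exact (via the signed-rank distribution)
#' when there are no ties among at most `exactMax` non-zero pairs, and the
#' normal approximation otherwise. The effect size is r = |Z| / sqrt(n)
#' over the non-zero pairs.
#'
#' @param x,y paired vectors (or `x` a vector of differences with
#'   `y = NULL`).
#' @param exactMax largest n for the exact p-value (default 25).
#' @return list (V, Z, p, nNonzero, r).
#' @export
wilcoxonSignedRank <- function(x, y = NULL, exactMax = 25L) {
  d <- if (is.null(y)) x else {
    stopifnot(length(x) == length(y))
    x - y
  }
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(V = 0, Z = 0, p = 1, nNonzero = 0L, r = 0))
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  tieTab <- table(rk)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tieTab^3 - tieTab) / 48
  if (sigma2 <= 0)
    return(list(V = V, Z = 0, p = 1, nNonzero = n, r = 0))
  cc <- sign(V - mu) * 0.5
  Z <- (V - mu - cc) / sqrt(sigma2)
  hasTies <- anyDuplicated(abs(d)) > 0L
  if (n <= exactMax && !hasTies) {
    p <- if (V > mu) {
      2 * stats::psignrank(V - 1, n, lower.tail = FALSE)
    } else {
      2 * stats::psignrank(V, n)
    }
  } else {
    p <- 2 * stats::pnorm(-abs(Z))
  }
  list(V = V, Z = Z, p = min(p, 1), nNonzero = n, r = abs(Z) / sqrt(n))
}

#' Effect-size magnitude band
#'
#' Step function of the signed-rank effect size r, closed on the left:
#' r < 0.1 Negligible, 0.1 <= r < 0.3 Small, 0.3 <= r < 0.5 Moderate,
#' r >= 0.5 Large.
#'
#' @param r effect size in `[0, 1]`.
#' @return character magnitude label.
#' @export
effectMagnitude <- function(r) {
  cut(r, breaks = c(-Inf, 0.1, 0.3, 0.5, Inf), right = FALSE,
      labels = c("Negligible", "Small", "Moderate", "Large")) |>
    as.character()
}

#' Cohen's d with an asymptotic confidence interval
#'
#' Standardised mean difference with pooled SD; the CI uses the
#' large-sample variance approximation
#' `var(d) = (n1+n2)/(n1 n2) + d^2 / (2 (n1+n2))`.
#'
#' @param a,b numeric samples.
#' @param level confidence level (default 0.95).
#' @return list (d, ciLow, ciHigh).
#' @export
cohensD <- function(a, b, level = 0.95) {
  n1 <- length(a)
  n2 <- length(b)
  sp <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
               (n1 + n2 - 2))
  d <- if (sp == 0) 0 else (mean(a) - mean(b)) / sp
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(d = d, ciLow = d - z * se, ciHigh = d + z * se)
}

#' Paired comparison of two drugs' ITE distributions
#'
#' Signed-rank test on paired per-patient ITEs (same patients, same
#' order), with effect size r, magnitude band, and Cohen's d between the
#' two distributions.
#'
#' @param iteA,iteB outputs of [estimateIte()] for the same patients, or
#'   bare numeric ITE vectors.
#' @param drugA,drugB labels (taken from the data.frames when available).
#' @return one-row data.frame with medians/IQRs, the signed-rank results,
#'   r, magnitude, and Cohen's d with CI.
#' @export
pairedIteComparison <- function(iteA, iteB, drugA = NULL, drugB = NULL) {
  if (is.data.frame(iteA)) {
    if (is.data.frame(iteB) &&
        !identical(iteA$patient_id, iteB$patient_id))
      stop("paired comparison requires the same patients in the same order")
    drugA <- drugA %||% iteA$drug[1]
    iteA <- iteA$tau_hat
  }
  if (is.data.frame(iteB)) {
    drugB <- drugB %||% iteB$drug[1]
    iteB <- iteB$tau_hat
  }
  if (length(iteA) != length(iteB))
    stop("ITE vectors must have equal length")
  w <- wilcoxonSignedRank(iteA, iteB)
  cd <- cohensD(iteA, iteB)
  qa <- stats::quantile(iteA, c(0.25, 0.5, 0.75), names = FALSE)
  qb <- stats::quantile(iteB, c(0.25, 0.5, 0.75), names = FALSE)
  data.frame(
    drug_a = drugA %||% "A", drug_b = drugB %||% "B",
    median_a = qa[2], iqr_a_low = qa[1], iqr_a_high = qa[3],
    median_b = qb[2], iqr_b_low = qb[1], iqr_b_high = qb[3],
    cohens_d = cd$d, d_ci_low = cd$ciLow, d_ci_high = cd$ciHigh,
    V = w$V, Z = w$Z, p = w$p, r = w$r,
    magnitude = effectMagnitude(w$r),
    n = length(iteA), n_nonzero = w$nNonzero,
    stringsAsFactors = FALSE)
}

#' Subgroup summaries of the ITE distribution
#'
#' Per-subgroup medians, IQRs and kernel density estimates of tau_hat
#' across age bands, sex and SIMD deciles, plus a between-group dispersion
#' statistic (the maximum pairwise difference of subgroup medians) per
#' covariate.
#'
#' @param iteResult output of [estimateIte()].
#' @param demographics demographics covering the scored patients.
#' @param covariates subset of c("age_band", "sex", "simd_decile").
#' @return list with `summaries` (covariate, group, n, median, iqr_low,
#'   iqr_high), `dispersion` (covariate, max_median_diff) and `densities`
#'   (named list of `stats::density` objects).
#' @export
subgroupIteSummaries <- function(iteResult, demographics,
                                 covariates = c("age_band", "sex",
                                                "simd_decile")) {
  dm <- demographics[match(iteResult$patient_id, demographics$patient_id),
                     , drop = FALSE]
  dm$age_band <- ageBand(dm$age)
  covariates <- match.arg(covariates, c("age_band", "sex", "simd_decile"),
                          several.ok = TRUE)
  sums <- list()
  disp <- list()
  dens <- list()
  for (cv in covariates) {
    groups <- split(iteResult$tau_hat, dm[[cv]])
    empty <- lengths(groups) == 0L
    if (any(empty)) {
      warning("omitting empty subgroup(s): ",
              paste(names(groups)[empty], collapse = ", "))
      groups <- groups[!empty]
    }
    med <- vapply(groups, stats::median, 0)
    for (gname in names(groups)) {
      g <- groups[[gname]]
      q <- stats::quantile(g, c(0.25, 0.5, 0.75), names = FALSE)
      sums[[length(sums) + 1L]] <- data.frame(
        covariate = cv, group = gname, n = length(g), median = q[2],
        iqr_low = q[1], iqr_high = q[3], stringsAsFactors = FALSE)
      if (length(g) >= 2L)
        dens[[paste(cv, gname, sep = ":")]] <- stats::density(g)
    }
    disp[[length(disp) + 1L]] <- data.frame(
      covariate = cv,
      max_median_diff = if (length(med) > 1) max(dist(med)) else 0)
  }
  list(summaries = do.call(rbind, sums), dispersion = do.call(rbind, disp),
       densities = dens)
}

#' Ground-truth recovery metrics (simulation mode)
#'
#' Compares estimated ITEs with the simulator's true ITEs: bias
#' (mean error), RMSE over patients, PEHE (the same root-mean-square
#' quantity, reported under its causal-inference name), and the Spearman
#' rank correlation.
#'
#' @param iteResult output of [estimateIte()], or a numeric tau_hat vector.
#' @param truth ground-truth data.frame from [groundTruth()] (filtered to
#'   one drug), or a numeric true-ITE vector aligned with `iteResult`.
#' @return list (bias, rmse, pehe, spearman, n).
#' @export
recoveryReport <- function(iteResult, truth) {
  tauHat <- if (is.data.frame(iteResult)) iteResult$tau_hat else iteResult
  if (is.data.frame(truth)) {
    if (is.data.frame(iteResult)) {
      drug <- iteResult$drug[1]
      if ("drug" %in% names(truth))
        truth <- truth[truth$drug == drug, , drop = FALSE]
      truth <- truth$true_ite[match(iteResult$patient_id,
                                    truth$patient_id)]
    } else truth <- truth$true_ite
  }
  if (length(truth) != length(tauHat) || anyNA(truth))
    stop("ground truth missing or misaligned with the ITE result")
  err <- tauHat - truth
  list(bias = mean(err), rmse = sqrt(mean(err^2)),
       pehe = sqrt(mean(err^2)),
       spearman = if (stats::sd(truth) == 0 || stats::sd(tauHat) == 0)
         NA_real_ else stats::cor(tauHat, truth, method = "spearman"),
       n = length(err))
}
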