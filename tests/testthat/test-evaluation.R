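# Metric implementations are validated against independent brute-force
# oracles: exhaustive threshold enumeration for the PR curve, full
# sign-pattern enumeration for the signed-rank distribution.

# Brute-force AUPRC: enumerate every distinct threshold with explicit
# loops, then trapezoid.
auprcBrute <- function(y, s) {
  th <- sort(unique(s), decreasing = TRUE)
  prec <- rec <- numeric(0)
  for (t in th) {
    pred <- s >= t
    tp <- sum(pred & y == 1)
    prec <- c(prec, tp / sum(pred))
    rec <- c(rec, tp / sum(y == 1))
  }
  area <- 0
  prevR <- 0
  prevP <- prec[1]
  for (i in seq_along(th)) {
    area <- area + (rec[i] - prevR) * (prec[i] + prevP) / 2
    prevR <- rec[i]
    prevP <- prec[i]
  }
  area
}

test_that("AUPRC equals exhaustive threshold enumeration", {
  expect_equal(auprc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.1)),
               auprcBrute(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.1)))
  withr::with_seed(11, {
    for (i in 1:60) {
      n <- sample(2:20, 1)
      y <- stats::rbinom(n, 1, 0.4)
      if (sum(y) == 0) y[sample(n, 1)] <- 1
      s <- round(stats::runif(n), sample(c(1, 2, 6), 1))  # force ties too
      expect_equal(auprc(y, s), auprcBrute(y, s), tolerance = 1e-12)
    }
  })
})

test_that("AUPRC limits: perfect ranking and the no-skill baseline", {
  y <- rep(c(1, 0), c(4, 16))
  expect_equal(auprc(y, ifelse(y == 1, 0.9, 0.1) +
                       seq_along(y) * 1e-4), 1)
  expect_equal(auprc(y, rep(0.3, 20)), 0.2)  # constant score -> prevalence
  m <- classificationMetrics(y, ifelse(y == 1, 0.9, 0.1))
  expect_equal(unname(m), c(1, 1, 1))
})

test_that("F1 is invariant to duplicating the evaluation set", {
  withr::with_seed(2, {
    y <- stats::rbinom(40, 1, 0.3)
    s <- stats::runif(40)
    m1 <- classificationMetrics(y, s)
    m2 <- classificationMetrics(rep(y, 2), rep(s, 2))
    expect_equal(m1[["f1"]], m2[["f1"]])
    expect_equal(m1[["accuracy"]], m2[["accuracy"]])
  })
})

# Exact two-sided signed-rank p-value by enumerating all 2^n sign
# patterns of the (tie-free) absolute ranks.
wilcoxBrute <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vall <- grid %*% rk
  mu <- n * (n + 1) / 4
  mean(abs(Vall - mu) >= abs(V - mu))
}

test_that("signed-rank p-values match exact enumeration for small n", {
  withr::with_seed(13, {
    for (i in 1:25) {
      n <- sample(4:12, 1)
      d <- round(stats::rnorm(n), 6)
      while (anyDuplicated(abs(d)) || any(d == 0))
        d <- round(stats::rnorm(n), 6)
      w <- wilcoxonSignedRank(d)
      expect_equal(w$p, wilcoxBrute(d), tolerance = 1e-12)
      # agreement with the standard implementation
      ref <- stats::wilcox.test(d, exact = TRUE)
      expect_equal(w$V, unname(ref$statistic))
      expect_equal(w$p, ref$p.value, tolerance = 1e-12)
    }
  })
})

test_that("the normal approximation is close at moderate n", {
  withr::with_seed(14, {
    d <- stats::rnorm(50, mean = 0.25)
    while (anyDuplicated(abs(d)) || any(d == 0)) d <- stats::rnorm(50)
    w <- wilcoxonSignedRank(d)                   # n = 50 -> normal approx
    exact <- stats::wilcox.test(d, exact = TRUE)$p.value
    expect_lt(abs(w$p - exact), 0.01)
  })
})

test_that("the signed-rank statistic matches brute-force ranks with
           all-positive differences", {
  a <- c(2, 3, 4, 5)
  b <- c(1, 1, 1, 1)
  w <- wilcoxonSignedRank(a, b)
  # |d| = 1,2,3,4 -> ranks 1..4, all positive -> V = 10
  expect_equal(w$V, 10)
  expect_equal(w$nNonzero, 4L)
})

test_that("zero and tied differences are handled as specified", {
  w <- wilcoxonSignedRank(c(0, 0, 0))
  expect_equal(w$r, 0)
  expect_identical(effectMagnitude(w$r), "Negligible")
  wt <- wilcoxonSignedRank(c(1, 1, -1, 2, 0))   # ties + a zero
  expect_equal(wt$nNonzero, 4L)
  expect_true(is.finite(wt$Z) && wt$p <= 1)
})

test_that("magnitude banding reproduces the published cut-points", {
  expect_identical(effectMagnitude(0.602), "Large")
  expect_identical(effectMagnitude(0.497), "Moderate")
  expect_identical(effectMagnitude(0.202), "Small")
  # closed on the left at each boundary
  expect_identical(effectMagnitude(c(0.0999, 0.1, 0.2999, 0.3, 0.4999,
                                     0.5)),
                   c("Negligible", "Small", "Small", "Moderate",
                     "Moderate", "Large"))
})

test_that("Cohen's d and the paired comparison behave on hand cases", {
  a <- c(1, 2, 3, 4)
  b <- c(2, 3, 4, 5)
  cd <- cohensD(a, b)
  expect_equal(cd$d, -1 / sqrt(5 / 3))  # pooled sd of two sd = 1.29 sets
  expect_lt(cd$ciLow, cd$d)
  expect_gt(cd$ciHigh, cd$d)
  same <- pairedIteComparison(a, a, "X", "X")
  expect_equal(same$cohens_d, 0)
  expect_equal(same$r, 0)
  expect_error(pairedIteComparison(a, b[1:3]), "equal length")
})

test_that("subgroup summaries report dispersion of medians", {
  dm <- makeDemographics(40, age = rep(c(45, 72), each = 20),
                         sex = rep(c("F", "M"), 20))
  ite <- data.frame(patient_id = dm$patient_id, drug = "ACEI",
                    tau_hat = rep(c(0.1, -0.1), each = 20),
                    stringsAsFactors = FALSE)
  out <- subgroupIteSummaries(ite, dm, covariates = "age_band")
  expect_equal(out$dispersion$max_median_diff, 0.2)
  # identical ITEs across groups -> zero dispersion
  ite0 <- ite
  ite0$tau_hat <- 0.05
  out0 <- subgroupIteSummaries(ite0, dm, covariates = c("age_band", "sex"))
  expect_true(all(out0$dispersion$max_median_diff == 0))
  # a single group reproduces the overall summary
  dmF <- makeDemographics(40, age = 50, sex = "F")
  iteF <- data.frame(patient_id = dmF$patient_id, drug = "ACEI",
                     tau_hat = ite$tau_hat, stringsAsFactors = FALSE)
  one <- subgroupIteSummaries(iteF, dmF, covariates = "sex")
  expect_equal(nrow(one$summaries), 1)
  expect_equal(one$summaries$median, stats::median(iteF$tau_hat))
  expect_equal(one$summaries$n, nrow(iteF))
  expect_equal(one$dispersion$max_median_diff, 0)
})

test_that("recovery metrics satisfy their identities", {
  tau <- c(-0.1, 0, 0.1, 0.2)
  r0 <- recoveryReport(tau, tau)
  expect_equal(r0$bias, 0)
  expect_equal(r0$pehe, 0)
  expect_equal(r0$spearman, 1)
  r1 <- recoveryReport(tau + 0.05, tau)
  expect_equal(r1$bias, 0.05)
  expect_equal(r1$pehe, 0.05)
  expect_gte(r1$pehe, abs(r1$bias))
  withr::with_seed(4, {
    tstar <- stats::rnorm(10000, 0, 0.05)
    perm <- sample(tstar)
    expect_lt(abs(recoveryReport(perm, tstar)$spearman), 0.05)
  })
  expect_error(recoveryReport(tau, tau[1:2]), "misaligned")
})

test_that("cross-validation evaluates fold-held-out predictions", {
  w <- smallWorld()
  # a factory whose predictions encode the separable marker token
  vt <- NULL
  oracleFactory <- function(encoded, y, seed) {
    vtab <- vocabTokens(encoded@vocab)
    marker <- vtab$id[vtab$token == "0103050"]
    functionRiskModel(function(enc) {
      hit <- apply(tokenIds(enc), 1, function(r) any(r == marker))
      ifelse(hit, 0.9, 0.1)
    })
  }
  # label = the same marker -> a perfect classifier on every fold
  vocab <- buildVocabulary(w$events)
  encAll <- encodePatients(w$labels$patient_id, w$events, w$demographics,
                           w$wave, vocab, maxLen = 32L)
  vtab <- vocabTokens(vocab)
  marker <- vtab$id[vtab$token == "0103050"]
  yMark <- as.integer(apply(tokenIds(encAll), 1,
                            function(r) any(r == marker)))
  cohort <- w$cohort
  cohort@labels$Y <- yMark
  cv <- crossValidate(cohort, w$events, w$demographics,
                      model = oracleFactory, k = 4L, maxLen = 32L,
                      seed = 3)
  expect_equal(cv$accuracy, rep(1, 4))
  expect_equal(cv$f1, rep(1, 4))
  expect_equal(cv$auprc, rep(1, 4))
  # constant predictions -> AUPRC equals the fold prevalence
  constFactory <- function(encoded, y, seed)
    functionRiskModel(function(enc) rep(0.5, nrow(enc@tokenIds)))
  cv0 <- crossValidate(cohort, w$events, w$demographics,
                       model = constFactory, k = 4L, maxLen = 32L,
                       seed = 3)
  folds <- txlearner:::stratifiedFolds(yMark, 4L, 3)
  for (j in 1:4)
    expect_equal(cv0$auprc[j], mean(yMark[folds == j]))
  expect_error(crossValidate(cohort, w$events, w$demographics, k = 1L))
})
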