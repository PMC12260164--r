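# Internal helpers shared across modules.

# Counter-based seed derivation: per-patient (and per-purpose) streams are
# derived from one master seed so that growing nPatients leaves earlier
# patients' draws untouched. Kept within 2^31 - 1 for R's integer range.
deriveSeed <- function(seed, counter, purpose = 0L) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(counter) * 7919 +
                as.numeric(purpose) * 104729) %% 2147483647)
}

# Evaluate an expression under a local RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

clip01 <- function(x) pmin(1, pmax(0, x))

startsWithAny <- function(x, prefixes) {
  out <- rep(FALSE, length(x))
  for (p in prefixes) out <- out | startsWith(x, p)
  out
}

#' Percentage of a count, rounded for reporting
#'
#' Cohort-summary convenience: `100 * n / total` rounded to `digits`
#' decimals, the convention used throughout the demographic tables.
#'
#' @param n count of interest.
#' @param total denominator count.
#' @param digits decimal places (default 1).
#' @return numeric percentage.
#' @examples
#' percentOf(23521, 244840)  # 9.6
#' @export
percentOf <- function(n, total, digits = 1) {
  round(100 * n / total, digits)
}

#' Undersampling keep-fraction from wave case counts
#'
#' The fraction of wave-1 outcome-negative patients retained during
#' stratified undersampling: the number of wave-1 cases divided by the
#' number of wave-2 cases.
#'
#' @param casesWave1,casesWave2 case counts in the two waves.
#' @return numeric ratio (no rounding applied).
#' @examples
#' undersamplingRatio(5344, 23521)
#' @export
undersamplingRatio <- function(casesWave1, casesWave2) {
  stopifnot(casesWave2 > 0)
  casesWave1 / casesWave2
}

# Truncated-normal mean on [a, b] for N(mu, sd): used to centre the
# simulator's analytic intercepts.
truncNormMean <- function(mu, sd, a, b) {
  al <- (a - mu) / sd
  be <- (b - mu) / sd
  mu + sd * (stats::dnorm(al) - stats::dnorm(be)) /
    (stats::pnorm(be) - stats::pnorm(al))
}

# Draws from N(mu, sd) truncated to [a, b] by inverse-CDF.
rtruncNorm <- function(n, mu, sd, a, b) {
  pl <- stats::pnorm(a, mu, sd)
  pu <- stats::pnorm(b, mu, sd)
  stats::qnorm(stats::runif(n, pl, pu), mu, sd)
}
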