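#' Gini coefficient / lognormal sigma conversions
#'
#' For a lognormal distribution with log-scale standard deviation sigma, the
#' Gini coefficient is exactly G = 2 * pnorm(sigma / sqrt(2)) - 1, so
#' sigma = sqrt(2) * qnorm((G + 1) / 2). Similarly the coefficient of
#' variation satisfies CV^2 = exp(sigma^2) - 1, giving
#' sigma = sqrt(log(1 + CV^2)). These exact identities are used instead of
#' tabulated approximations; each pair round-trips to better than 1e-9.
#'
#' @param gini Gini coefficient in (0, 1).
#' @param sigma lognormal log-scale standard deviation, > 0.
#' @param cv coefficient of variation, > 0.
#' @return The converted parameter (vectorized).
#' @examples
#' sigmaFromGini(0.30)            # ~0.5449
#' giniFromSigma(sigmaFromGini(0.42))  # 0.42
#' sigmaFromCv(0.25)              # ~0.24622
#' @name giniSigma
NULL

#' @rdname giniSigma
#' @export
sigmaFromGini <- function(gini) {
  if (!is.numeric(gini) || any(!is.finite(gini)) ||
      any(gini <= 0) || any(gini >= 1))
    stop("gini must lie in (0, 1)")
  sqrt(2) * qnorm((gini + 1) / 2)
}

#' @rdname giniSigma
#' @export
giniFromSigma <- function(sigma) {
  if (!is.numeric(sigma) || any(!is.finite(sigma)) || any(sigma <= 0))
    stop("sigma must be > 0")
  2 * pnorm(sigma / sqrt(2)) - 1
}

#' @rdname giniSigma
#' @export
sigmaFromCv <- function(cv) {
  if (!is.numeric(cv) || any(!is.finite(cv)) || any(cv <= 0))
    stop("cv must be > 0")
  sqrt(log(1 + cv^2))
}

#' @rdname giniSigma
#' @export
cvFromSigma <- function(sigma) {
  if (!is.numeric(sigma) || any(!is.finite(sigma)) || any(sigma <= 0))
    stop("sigma must be > 0")
  sqrt(exp(sigma^2) - 1)
}

#' Construct an inequality model
#'
#' Exactly one of \code{gini} or \code{cv} must be supplied; the other and
#' the lognormal spread sigma are derived through the exact lognormal
#' identities (see [sigmaFromGini()]). The supplied statistic is interpreted
#' as the inequality of the dietary energy consumption distribution itself.
#'
#' @param gini Gini coefficient in (0, 1), or NULL.
#' @param cv coefficient of variation > 0, or NULL.
#' @return An [InequalityModel-class].
#' @examples
#' InequalityModel(gini = 0.30)
#' InequalityModel(cv = 0.25)
#' @export
InequalityModel <- function(gini = NULL, cv = NULL) {
  if (is.null(gini) == is.null(cv))
    stop("exactly one of gini or cv must be supplied")
  if (!is.null(gini)) {
    sigma <- sigmaFromGini(gini)
    cv <- cvFromSigma(sigma)
  } else {
    sigma <- sigmaFromCv(cv)
    gini <- giniFromSigma(sigma)
  }
  new("InequalityModel", gini = as.numeric(gini), cv = as.numeric(cv),
      sigma = as.numeric(sigma))
}

#' @describeIn InequalityModel accessor for the lognormal spread sigma.
#' @param x an InequalityModel.
#' @export
inequalitySigma <- function(x) {
  stopifnot(is(x, "InequalityModel"))
  x@sigma
}

#' @describeIn InequalityModel accessor for the Gini coefficient.
#' @export
inequalityGini <- function(x) {
  stopifnot(is(x, "InequalityModel"))
  x@gini
}

#' Construct a consumption distribution
#'
#' The lognormal model of habitual dietary energy consumption, parameterized
#' so that its arithmetic mean equals the mean dietary energy supply:
#' \code{muLog = log(meanDes) - sigma^2 / 2}.
#'
#' @param meanDes mean dietary energy supply, kcal/capita/day, > 0.
#' @param sigma lognormal log-scale spread (> 0), or an
#'   [InequalityModel-class] from which it is taken.
#' @return A [ConsumptionDistribution-class].
#' @examples
#' dist <- ConsumptionDistribution(2100, InequalityModel(gini = 0.30))
#' pou(dist, 1800)  # ~0.4958
#' @export
ConsumptionDistribution <- function(meanDes, sigma) {
  if (is(sigma, "InequalityModel")) sigma <- sigma@sigma
  if (!is.numeric(meanDes) || length(meanDes) != 1L || meanDes <= 0)
    stop("meanDes must be a single positive number")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a single positive number")
  new("ConsumptionDistribution", meanDes = as.numeric(meanDes),
      sigma = as.numeric(sigma),
      muLog = log(meanDes) - sigma^2 / 2)
}

#' Prevalence of undernourishment (PoU)
#'
#' The fraction of the population whose habitual dietary energy consumption
#' falls below the minimum dietary energy requirement: the lognormal CDF at
#' the cut-off, \code{pnorm((log(mder) - muLog) / sigma)}.
#'
#' @param dist a [ConsumptionDistribution-class].
#' @param mder minimum dietary energy requirement, kcal/capita/day, > 0.
#' @return PoU as a fraction in [0, 1]. Percentage formatting is left to the
#'   presentation layer.
#' @export
pou <- function(dist, mder) {
  stopifnot(is(dist, "ConsumptionDistribution"))
  if (!is.numeric(mder) || any(!is.finite(mder)) || any(mder <= 0))
    stop("mder must be > 0")
  pnorm((log(mder) - dist@muLog) / dist@sigma)
}

#' Sample from a consumption distribution
#'
#' Monte Carlo draws from the lognormal consumption model, used as the
#' independent oracle for the closed-form prevalence. Deterministic for a
#' fixed seed; the caller's RNG state is left untouched.
#'
#' @param dist a [ConsumptionDistribution-class].
#' @param n number of draws, >= 1.
#' @param seed integer RNG seed.
#' @return Numeric vector of \code{n} consumption values (kcal/capita/day).
#' @export
sampleConsumption <- function(dist, n, seed) {
  stopifnot(is(dist, "ConsumptionDistribution"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be >= 1")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  rlnorm(n, meanlog = dist@muLog, sdlog = dist@sigma)
}

#' Empirical Gini coefficient
#'
#' Sample Gini of a vector of non-negative values, computed from the sorted
#' values as \code{sum((2*i - n - 1) * x_(i)) / (n^2 * mean(x))}.
#'
#' @param x numeric vector of non-negative values with positive mean.
#' @return Gini coefficient in [0, 1).
#' @export
giniEmpirical <- function(x) {
  if (!is.numeric(x) || length(x) < 1L || any(x < 0) || mean(x) <= 0)
    stop("x must be non-negative with positive mean")
  n <- length(x)
  xs <- sort(x)
  sum((2 * seq_len(n) - n - 1) * xs) / (n^2 * mean(xs))
}
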