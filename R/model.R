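#' @include AllClasses.R design.R
NULL

# The state-space model, term by term.
#
# State process:   N[s,t] = N[s,t-1] * exp(r[s,t]), with the growth rate a
#                  first-order random walk r[s,t] ~ N(r[s,t-1], sigma_year^2)
#                  anchored at r[s,1] ~ N(0, sigma_year^2).
# Initial state:   log N[s,1] ~ N(mu, sigma_site^2).
# Seasonality:     delta[1] = 0; delta[m] ~ N(delta[m-1], sigma_month1^2);
#                  alpha[m,t] ~ N(delta[m], sigma_month2^2).
# Observation:     log(count + 1) ~ Student-t(log N[s,t] + alpha[m,t]
#                  + log p[i,s,t], sigma_i, nu), nu fixed at 4.
# Detection:       p[i,s,t] = inverse-logit(beta_i + gamma[i,s,t]) with
#                  beta2 = 0 fixed, so p is a conditional detection index
#                  anchored at 0.5, not an absolute probability.

#' One state-process step
#'
#' Stochastic exponential growth: the abundance index in year t is the
#' previous year's index scaled by \code{exp(r)}.
#'
#' @param nPrev abundance index in year t - 1 (must be positive).
#' @param r instantaneous growth rate from year t - 1 to t.
#' @return \code{nPrev * exp(r)}.
#' @examples
#' stateUpdate(50, log(2))  # one doubling: 100
#' @export
stateUpdate <- function(nPrev, r) {
  if (any(!is.finite(nPrev)) || any(nPrev <= 0))
    stop("nPrev must be positive: the abundance index cannot reach 0")
  nPrev * exp(r)
}

#' Log-density of a growth-rate innovation
#'
#' First-order random walk: \code{r_t ~ Normal(r_prev, sigma_year^2)}.
#'
#' @param rT growth rate in year t.
#' @param rPrev growth rate in year t - 1.
#' @param sigmaYear positive innovation SD.
#' @return the Normal log-density.
#' @export
growthRateLogpdf <- function(rT, rPrev, sigmaYear) {
  if (!is.numeric(sigmaYear) || any(sigmaYear <= 0))
    stop("sigmaYear must be positive")
  stats::dnorm(rT, mean = rPrev, sd = sigmaYear, log = TRUE)
}

#' Log-density of the initial state
#'
#' \code{log N[s,1] ~ Normal(mu, sigma_site^2)}.
#'
#' @param logN1 initial log abundance.
#' @param mu expected initial log abundance.
#' @param sigmaSite positive between-site SD.
#' @return the Normal log-density.
#' @export
initialStateLogpdf <- function(logN1, mu, sigmaSite) {
  if (!is.numeric(sigmaSite) || any(sigmaSite <= 0))
    stop("sigmaSite must be positive")
  stats::dnorm(logN1, mean = mu, sd = sigmaSite, log = TRUE)
}

#' Joint log-density of the seasonal pattern
#'
#' Sums the month-effect random walk over months m >= 2 (September is the
#' anchor, \code{delta[1] = 0}) and the interannual seasonal deviations
#' \code{alpha[m,t] ~ Normal(delta[m], sigma_month2^2)} over all months and
#' years.
#'
#' @param delta month effects, length M, \code{delta[1]} must be 0.
#' @param alpha months x years matrix of seasonal offsets.
#' @param sigmaMonth1 SD of the month-to-month random walk.
#' @param sigmaMonth2 SD of interannual deviations.
#' @return scalar log-density.
#' @export
seasonalLogpdf <- function(delta, alpha, sigmaMonth1, sigmaMonth2) {
  if (sigmaMonth1 <= 0) stop("sigmaMonth1 must be positive")
  if (sigmaMonth2 <= 0) stop("sigmaMonth2 must be positive")
  if (delta[1] != 0)
    stop("delta[1] must be 0 (September identifiability anchor)")
  alpha <- as.matrix(alpha)
  if (nrow(alpha) != length(delta))
    stop("alpha must have one row per month effect")
  M <- length(delta)
  lp <- 0
  if (M > 1L)
    lp <- sum(stats::dnorm(delta[-1], mean = delta[-M], sd = sigmaMonth1,
                           log = TRUE))
  lp + sum(stats::dnorm(alpha, mean = delta[row(alpha)], sd = sigmaMonth2,
                        log = TRUE))
}

#' Conditional detection index
#'
#' Inverse-logit of the cell's linear predictor \code{beta + gamma}. With the
#' ground anchor \code{beta2 = 0} this is 0.5 for the baseline cell: a
#' detection index conditional on that anchor, not an absolute detection
#' probability.
#'
#' @param beta baseline logit of the method.
#' @param gamma logit offset of the cell (0 for baseline cells).
#' @return probability index strictly in (0, 1).
#' @examples
#' detectionProbability(0, 0)  # the anchored baseline: 0.5
#' @export
detectionProbability <- function(beta, gamma) {
  stats::plogis(beta + gamma)
}

#' Observation log-density of one transformed count
#'
#' Heavy-tailed log-Student error: the log-scale observation has a Student-t
#' density with location \code{logN + alpha + log(p)}, scale \code{sigmaObs}
#' and \code{nu} degrees of freedom. The low default \code{nu = 4} buffers
#' occasional large counting errors (a missed flock, double counts) that a
#' log-Normal would penalise too strongly.
#'
#' @param logCount observed log-scale count, \code{log(count + 1)}.
#' @param logN latent log abundance index.
#' @param alpha seasonal offset of the (month, year).
#' @param p detection index in (0, 1).
#' @param sigmaObs positive observation scale of the method.
#' @param nu positive degrees of freedom.
#' @return the Student-t log-density.
#' @export
observationLogpdf <- function(logCount, logN, alpha, p, sigmaObs, nu) {
  if (any(sigmaObs <= 0)) stop("sigmaObs must be positive")
  if (any(nu <= 0)) stop("nu must be positive")
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly in (0, 1)")
  loc <- logN + alpha + log(p)
  stats::dt((logCount - loc) / sigmaObs, df = nu, log = TRUE) - log(sigmaObs)
}

#' Log-density of a prior entry evaluated at a value
#'
#' @param entry one element of a \code{\linkS4class{PriorSpec}}.
#' @param x value(s) to evaluate at.
#' @return log prior density.
#' @export
priorLogpdf <- function(entry, x) {
  switch(entry$family,
    normal = stats::dnorm(x, entry$pars[1], entry$pars[2], log = TRUE),
    halfnormal = ifelse(x < 0, -Inf,
      log(2) + stats::dnorm(x, 0, entry$pars[1], log = TRUE)),
    stop("unsupported prior family: ", entry$family))
}

#' Joint log-density of parameters, latent states and data
#'
#' Adds the initial-state, growth-rate, seasonal and observation terms
#' (missing cells are omitted from the observation sum: with a fully latent
#' state process this marginalisation is exact), plus, when a
#' \code{\linkS4class{PriorSpec}} is supplied, the log prior density of every
#' free top-level parameter.
#'
#' @param params a \code{\linkS4class{ModelParameters}} with latent states
#'   filled in.
#' @param data a \code{\linkS4class{SurveyDataset}}.
#' @param design the matching \code{\linkS4class{DetectionDesign}}.
#' @param priors optional \code{\linkS4class{PriorSpec}}; when \code{NULL}
#'   only the generative terms (state + seasonal + observation) are summed.
#' @return scalar log-density.
#' @export
jointLogDensity <- function(params, data, design, priors = NULL) {
  st <- data@structure
  S <- st@nSites; T <- st@nYears; M <- st@nMonths
  if (!identical(dim(params@r), c(S, T)) || length(params@logN1) != S ||
      length(params@delta) != M || !identical(dim(params@alpha), c(M, T)))
    stop("latent state dimensions do not match the dataset structure")

  lp <- sum(initialStateLogpdf(params@logN1, params@mu, params@sigmaSite))
  # growth-rate random walk, anchored at r[s,1] ~ N(0, sigma_year^2)
  lp <- lp + sum(growthRateLogpdf(params@r[, 1], 0, params@sigmaYear))
  if (T > 1L)
    lp <- lp + sum(growthRateLogpdf(params@r[, -1, drop = FALSE],
                                    params@r[, -T, drop = FALSE],
                                    params@sigmaYear))
  lp <- lp + seasonalLogpdf(params@delta, params@alpha,
                            params@sigmaMonth1, params@sigmaMonth2)

  logN <- latentLogN(params)
  pArr <- detectionArray(design, params)
  y <- data@logCounts
  for (i in 1:2) {
    obs <- which(!is.na(y[i, , , , drop = FALSE]), arr.ind = TRUE)
    if (nrow(obs) == 0L) next
    m <- obs[, 2]; s <- obs[, 3]; t <- obs[, 4]
    lp <- lp + sum(observationLogpdf(
      y[cbind(i, m, s, t)], logN[cbind(s, t)], params@alpha[cbind(m, t)],
      pArr[cbind(i, s, t)], params@sigmaObs[i], params@nu))
  }

  if (!is.null(priors)) {
    vec <- topLevelVector(params)
    for (nm in names(priors@entries))
      lp <- lp + priorLogpdf(priors@entries[[nm]], vec[[nm]])
  }
  if (!is.finite(lp))
    stop("joint log-density is not finite; check scales and latent states")
  lp
}

#' Latent log-abundance surface implied by the states
#'
#' \code{log N[s,t] = log N[s,1] + sum of r[s,2..t]}: the cumulated random
#' walk, so reconstructed \code{N} is strictly positive by construction.
#'
#' @param params a \code{\linkS4class{ModelParameters}} with \code{logN1} and
#'   \code{r} present.
#' @return sites x years matrix of log abundance indices.
#' @export
latentLogN <- function(params) {
  S <- length(params@logN1); T <- ncol(params@r)
  if (!S || !T) stop("latent states are empty")
  incr <- params@r
  incr[, 1] <- 0   # r[s,1] anchors the walk but precedes the first transition
  params@logN1 + t(apply(incr, 1, cumsum))
}
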