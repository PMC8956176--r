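#' @include AllClasses.R model.R dataset.R
NULL

#' Deterministic seed splitting
#'
#' Derives independent substream seeds from one master seed so the truth,
#' observation-noise and missingness draws can be varied independently. Pure
#' integer arithmetic below 2^31.
#'
#' @param seed master seed (integer).
#' @param index substream index (integer, vectorised).
#' @return integer seed(s).
#' @export
splitSeed <- function(seed, index) {
  as.integer((as.double(seed) %% 2147483647 * 7919 + 104729 * as.double(index)) %%
               2147483647)
}

#' Generate the latent truth of a synthetic study
#'
#' Runs the state and seasonal processes forward at the supplied generating
#' parameters: initial log abundances from the initial-state model, growth
#' rates from their first-order random walk (anchored at
#' \code{r[s,1] ~ N(0, sigma_year^2)}), month effects from the seasonal
#' random walk with the September anchor \code{delta[1] = 0}, and seasonal
#' offsets around the month effects. Deterministic given \code{seed}.
#'
#' @param structure a \code{\linkS4class{StudyStructure}}.
#' @param parameters a \code{\linkS4class{ModelParameters}} (latent slots are
#'   overwritten).
#' @param seed integer seed.
#' @return a list with elements \code{parameters} (latents filled in),
#'   \code{latentAbundance} (sites x years matrix of N), \code{detection}
#'   (2 x sites x years detection-index array), \code{design}, and
#'   \code{logDensity}, the accumulated log-density of every draw made (the
#'   generative share of \code{\link{jointLogDensity}}).
#' @export
generateTruth <- function(structure, parameters, seed) {
  stopifnot(is(structure, "StudyStructure"), is(parameters, "ModelParameters"))
  validObject(parameters)
  S <- structure@nSites; T <- structure@nYears; M <- structure@nMonths
  set.seed(seed)

  logN1 <- stats::rnorm(S, parameters@mu, parameters@sigmaSite)
  r <- matrix(0, S, T)
  r[, 1] <- stats::rnorm(S, 0, parameters@sigmaYear)
  for (t in seq_len(T)[-1])
    r[, t] <- stats::rnorm(S, r[, t - 1], parameters@sigmaYear)
  delta <- numeric(M)
  for (m in seq_len(M)[-1])
    delta[m] <- stats::rnorm(1, delta[m - 1], parameters@sigmaMonth1)
  alpha <- matrix(stats::rnorm(M * T, delta, parameters@sigmaMonth2), M, T)

  params <- parameters
  params@logN1 <- logN1; params@r <- r; params@delta <- delta
  params@alpha <- alpha

  ld <- sum(initialStateLogpdf(logN1, parameters@mu, parameters@sigmaSite)) +
    sum(growthRateLogpdf(r[, 1], 0, parameters@sigmaYear)) +
    sum(growthRateLogpdf(r[, -1, drop = FALSE], r[, -T, drop = FALSE],
                         parameters@sigmaYear)) +
    seasonalLogpdf(delta, alpha, parameters@sigmaMonth1, parameters@sigmaMonth2)

  design <- buildDetectionDesign(structure)
  list(parameters = params,
       latentAbundance = exp(latentLogN(params)),
       detection = detectionArray(design, params),
       design = design,
       logDensity = ld)
}

# Student-t draws for every (method, month, site, year) cell at the model's
# observation locations; shared by the generator and the posterior
# predictive check so a point-mass posterior reproduces the generator.
drawLogObservations <- function(logN, alpha, pArr, sigmaObs, nu, seed) {
  S <- nrow(logN); T <- ncol(logN); M <- nrow(alpha)
  set.seed(seed)
  y <- array(NA_real_, c(2L, M, S, T))
  tdev <- array(stats::rt(2L * M * S * T, df = nu), c(2L, M, S, T))
  for (i in 1:2) for (m in seq_len(M)) {
    loc <- log(pArr[i, , , drop = TRUE]) + logN +
      matrix(alpha[m, ], S, T, byrow = TRUE)
    y[i, m, , ] <- loc + sigmaObs[i] * tdev[i, m, , ]
  }
  y
}

#' Generate observed counts from a simulated truth
#'
#' For every cell, draws the log-scale observation from a Student-t centred
#' at \code{log N[s,t] + alpha[m,t] + log p[i,s,t]} with the method's scale
#' and \code{nu} degrees of freedom, maps it back to an integer count via
#' \code{count = max(0, round(exp(y) - 1))} (the package's \code{log(count +
#' 1)} convention), then applies missingness: Bernoulli per cell at the
#' structure's (method, area) rate, plus deterministic censoring of aerial
#' cells before a site's introduction year. Deterministic given \code{seed};
#' noise and missingness use independent substreams of it.
#'
#' @param truth the list returned by \code{\link{generateTruth}}.
#' @param structure the same structure the truth was generated under.
#' @param seed integer seed.
#' @param exact when \code{TRUE} the returned dataset's \code{logCounts} hold
#'   the continuous draws themselves (no rounding), so the joint density of
#'   the generated record can be evaluated exactly.
#' @return a \code{\linkS4class{SurveyDataset}} with attribute
#'   \code{"logDensity"}: the generative observation log-density accumulated
#'   over the non-missing cells (at the continuous draws).
#' @export
generateCounts <- function(truth, structure, seed, exact = FALSE) {
  params <- truth$parameters
  S <- structure@nSites; T <- structure@nYears; M <- structure@nMonths
  if (length(params@logN1) != S || ncol(params@r) != T ||
      length(params@delta) != M)
    stop("truth and structure disagree on dimensions")
  logN <- latentLogN(params)
  y <- drawLogObservations(logN, params@alpha, truth$detection,
                           params@sigmaObs, params@nu, splitSeed(seed, 1L))

  # missingness: MCAR per (method, area) plus aerial pre-introduction censoring
  set.seed(splitSeed(seed, 2L))
  miss <- array(FALSE, dim(y))
  mr <- structure@missingnessRate
  for (i in 1:2) for (s in seq_len(S)) {
    rate <- mr[kMethods[i], structure@areaOfSite[s]]
    miss[i, , s, ] <- stats::runif(M * T) < rate
  }
  for (s in seq_len(S))
    if (structure@aerialIntroYear[s] > 1L)
      miss[1, , s, seq_len(structure@aerialIntroYear[s] - 1L)] <- TRUE

  obsLd <- 0
  for (i in 1:2) {
    yi <- y[i, , , , drop = FALSE]; mi <- miss[i, , , , drop = FALSE]
    idx <- which(!mi, arr.ind = TRUE)
    m <- idx[, 2]; s <- idx[, 3]; t <- idx[, 4]
    obsLd <- obsLd + sum(observationLogpdf(
      yi[cbind(1L, m, s, t)], logN[cbind(s, t)], params@alpha[cbind(m, t)],
      truth$detection[cbind(i, s, t)], params@sigmaObs[i], params@nu))
  }

  # counts stay double: extreme prior draws can exceed integer range
  counts <- round(exp(y) - 1)
  counts[counts < 0] <- 0
  counts[miss] <- NA_real_
  y[miss] <- NA_real_
  ds <- surveyDataset(counts, structure, species = "synthetic",
                      logCounts = if (exact) y else NULL)
  attr(ds, "logDensity") <- obsLd
  ds
}

#' Named synthetic fixtures
#'
#' Bundles a study structure, the package's fixed generating parameters and a
#' seed into a named, versioned configuration. \code{"tiny"} (6 sites, 10
#' years) runs the full pipeline inside a test suite; \code{"small"} is an
#' intermediate scale; \code{"full"} reproduces the full study design (40
#' sites, 44 years, 7 months).
#'
#' @param scale \code{"tiny"}, \code{"small"} or \code{"full"}.
#' @param seed integer seed (defaults to a fixed fixture seed).
#' @return list with elements \code{structure}, \code{parameters},
#'   \code{seed}, \code{scale}, \code{version}.
#' @export
makeFixture <- function(scale = c("tiny", "small", "full"), seed = 20260924L) {
  scale <- match.arg(scale)
  list(structure = studyStructureOf(scale), parameters = fixtureParameters(),
       seed = as.integer(seed), scale = scale, version = "1")
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper: \code{\link{generateTruth}} then
#' \code{\link{generateCounts}} under split substreams of one seed.
#'
#' @param fixture a fixture list from \code{\link{makeFixture}} (or any list
#'   with \code{structure}, \code{parameters}, \code{seed}).
#' @param seed optional seed overriding the fixture's.
#' @param exact passed to \code{\link{generateCounts}}.
#' @return list with \code{truth} and \code{dataset}.
#' @export
simulateSurvey <- function(fixture, seed = fixture$seed, exact = FALSE) {
  truth <- generateTruth(fixture$structure, fixture$parameters,
                         splitSeed(seed, 11L))
  dataset <- generateCounts(truth, fixture$structure, splitSeed(seed, 12L),
                            exact = exact)
  list(truth = truth, dataset = dataset)
}

#' Write a generated truth record to JSON
#'
#' @param truth list from \code{\link{generateTruth}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeTruth <- function(truth, path) {
  p <- truth$parameters
  obj <- list(parameters = list(
    mu = p@mu, sigma_site = p@sigmaSite, sigma_year = p@sigmaYear,
    sigma_month1 = p@sigmaMonth1, sigma_month2 = p@sigmaMonth2,
    sigma_obs = as.list(p@sigmaObs), nu = p@nu,
    beta1 = p@beta1, beta2 = p@beta2,
    gamma_aerial = as.list(p@gammaAerial),
    gamma_ground = as.list(p@gammaGround)),
    logN1 = p@logN1, r = p@r, delta = p@delta, alpha = p@alpha,
    latent_abundance = truth$latentAbundance,
    log_density = truth$logDensity)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
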