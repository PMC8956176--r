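#' @include AllClasses.R priors.R design.R
NULL

#' Construct an McmcConfig
#'
#' @param nIterations post-adaptation iterations per chain (including
#'   burn-in); each chain retains \code{(nIterations - nBurnin) / thin}
#'   draws.
#' @param nBurnin discarded initial iterations.
#' @param thin thinning interval.
#' @param nChains number of chains (>= 2).
#' @param seed master seed for chain RNGs and dispersed initial values.
#' @param initDispersion over-dispersion factor for prior-drawn initials.
#' @return a validated \code{\linkS4class{McmcConfig}}.
#' @export
mcmcConfig <- function(nIterations = 4000L, nBurnin = 1000L, thin = 3L,
                       nChains = 3L, seed = 1L, initDispersion = 2) {
  new("McmcConfig", nIterations = as.integer(nIterations),
      nBurnin = as.integer(nBurnin), thin = as.integer(thin),
      nChains = as.integer(nChains), seed = as.integer(seed),
      initDispersion = as.numeric(initDispersion))
}

#' The full-scale chain configuration
#'
#' 40,000 posterior iterations per chain with the first 1,500 discarded as
#' burn-in, every 10th sample retained, three chains with dispersed initial
#' values.
#'
#' @param seed master seed.
#' @return an \code{\linkS4class{McmcConfig}}.
#' @export
fullMcmcConfig <- function(seed = 1L) {
  mcmcConfig(nIterations = 40000L, nBurnin = 1500L, thin = 10L, nChains = 3L,
             seed = seed, initDispersion = 2)
}

# BUGS-language model code. The seasonal random walk is written in
# innovation form (delta deterministic from stochastic increments), which is
# the same density, and keeps deterministic and stochastic nodes in separate
# arrays as BUGS requires.
jagsModelString <- function(priors) {
  nodeOf <- c(mu = "mu", sigma_site = "sigmaSite", sigma_year = "sigmaYear",
              sigma_month1 = "sigmaMonth1", sigma_month2 = "sigmaMonth2",
              sigma_obs_aerial = "sigmaObs[1]", sigma_obs_ground = "sigmaObs[2]",
              beta1 = "beta1", gamma_obs2 = "gammaA[1]", gamma_obs3 = "gammaA[2]",
              gamma_palissade = "gammaG[1]", gamma_rnn = "gammaG[2]",
              gamma_tdv_old = "gammaG[3]", gamma_tdv_new = "gammaG[4]")
  priorLine <- function(nm) {
    e <- priors@entries[[nm]]
    node <- nodeOf[[nm]]
    switch(e$family,
      normal = sprintf("  %s ~ dnorm(%.17g, %.17g)", node, e$pars[1],
                       1 / e$pars[2]^2),
      halfnormal = sprintf("  %s ~ dnorm(0, %.17g) T(0,)", node,
                           1 / e$pars[1]^2))
  }
  paste(c(
    "model {",
    vapply(kFreeParameters, priorLine, character(1)),
    "  tauSite <- pow(sigmaSite, -2)",
    "  tauYear <- pow(sigmaYear, -2)",
    "  tauMonth1 <- pow(sigmaMonth1, -2)",
    "  tauMonth2 <- pow(sigmaMonth2, -2)",
    "  for (i in 1:2) { tauObs[i] <- pow(sigmaObs[i], -2) }",
    "  for (s in 1:S) {",
    "    logN1[s] ~ dnorm(mu, tauSite)",
    "    logN[s, 1] <- logN1[s]",
    "    r[s, 1] ~ dnorm(0, tauYear)",
    "    for (t in 2:T) {",
    "      r[s, t] ~ dnorm(r[s, t - 1], tauYear)",
    "      logN[s, t] <- logN[s, t - 1] + r[s, t]",
    "    }",
    "  }",
    "  delta[1] <- 0",
    "  for (m in 2:M) {",
    "    eMonth[m - 1] ~ dnorm(0, tauMonth1)",
    "    delta[m] <- delta[m - 1] + eMonth[m - 1]",
    "  }",
    "  for (m in 1:M) { for (t in 1:T) { alpha[m, t] ~ dnorm(delta[m], tauMonth2) } }",
    "  eta[1] <- beta1",
    "  eta[2] <- beta1 + gammaA[1]",
    "  eta[3] <- beta1 + gammaA[2]",
    "  eta[4] <- beta2 + gammaG[1]",
    "  eta[5] <- beta2 + gammaG[2]",
    "  eta[6] <- beta2 + gammaG[3]",
    "  eta[7] <- beta2 + gammaG[4]",
    "  eta[8] <- beta2",
    "  for (k in 1:8) { p[k] <- ilogit(eta[k]) }",
    "  for (j in 1:J) {",
    "    y[j] ~ dt(logN[site[j], year[j]] + alpha[month[j], year[j]] + log(p[cell[j]]), tauObs[meth[j]], nu)",
    "  }",
    "}"), collapse = "\n")
}

# flatten the observed cells of a dataset for the sampler
observedCells <- function(dataset, design) {
  y <- dataset@logCounts
  idx <- which(!is.na(y), arr.ind = TRUE)
  colnames(idx) <- c("meth", "month", "site", "year")
  cell <- design@cells[cbind(idx[, "meth"], idx[, "site"], idx[, "year"])]
  list(y = y[idx], meth = idx[, "meth"], month = idx[, "month"],
       site = idx[, "site"], year = idx[, "year"],
       cell = match(cell, kDetectionCells))
}

# dispersed initial values: top-level parameters drawn from the prior with
# its spread inflated by the dispersion factor; latent states from the
# data-implied crude index with detection at the anchor value (p = 0.5)
chainInits <- function(dataset, priors, config, chain, dispersion) {
  st <- dataset@structure
  S <- st@nSites; T <- st@nYears; M <- st@nMonths
  set.seed(splitSeed(config@seed, 1000L + chain))
  drawInit <- function(nm) {
    e <- priors@entries[[nm]]
    if (!is.null(e$point)) return(e$point)
    switch(e$family,
      normal = stats::rnorm(1, e$pars[1], dispersion * e$pars[2]),
      halfnormal = abs(stats::rnorm(1, 0, dispersion * e$pars[1])) + 0.02)
  }
  v <- vapply(kFreeParameters, drawInit, numeric(1))
  crude <- apply(dataset@logCounts, c(3, 4), mean, na.rm = TRUE) - log(0.5)
  siteMean <- rowMeans(crude, na.rm = TRUE)
  siteMean[!is.finite(siteMean)] <- mean(crude[is.finite(crude)])
  crude[!is.finite(crude)] <- siteMean[row(crude)[!is.finite(crude)]]
  list(mu = v[["mu"]], sigmaSite = v[["sigma_site"]],
       sigmaYear = v[["sigma_year"]], sigmaMonth1 = v[["sigma_month1"]],
       sigmaMonth2 = v[["sigma_month2"]],
       sigmaObs = c(v[["sigma_obs_aerial"]], v[["sigma_obs_ground"]]),
       beta1 = v[["beta1"]],
       gammaA = c(v[["gamma_obs2"]], v[["gamma_obs3"]]),
       gammaG = c(v[["gamma_palissade"]], v[["gamma_rnn"]],
                  v[["gamma_tdv_old"]], v[["gamma_tdv_new"]]),
       logN1 = crude[, 1] + stats::rnorm(S, 0, 0.1),
       r = matrix(0, S, T), eMonth = rep(0, M - 1L),
       alpha = matrix(0, M, T),
       .RNG.name = "base::Mersenne-Twister",
       .RNG.seed = splitSeed(config@seed, 2000L + chain))
}

renameDraws <- function(nms) {
  fixed <- c(sigmaSite = "sigma_site", sigmaYear = "sigma_year",
             sigmaMonth1 = "sigma_month1", sigmaMonth2 = "sigma_month2",
             "sigmaObs[1]" = "sigma_obs_aerial",
             "sigmaObs[2]" = "sigma_obs_ground",
             "gammaA[1]" = "gamma_obs2", "gammaA[2]" = "gamma_obs3",
             "gammaG[1]" = "gamma_palissade", "gammaG[2]" = "gamma_rnn",
             "gammaG[3]" = "gamma_tdv_old", "gammaG[4]" = "gamma_tdv_new")
  pcells <- stats::setNames(paste0("p_", sub("^(aerial|ground)_", "",
                                             kDetectionCells)),
                            paste0("p[", 1:8, "]"))
  names(pcells) <- paste0("p[", 1:8, "]")
  map <- c(fixed, pcells)
  out <- nms
  hit <- nms %in% names(map)
  out[hit] <- map[nms[hit]]
  out
}

#' Fit the state-space model by MCMC
#'
#' Runs the Gibbs sampler (JAGS) on the joint model with the configured
#' chains, burn-in and thinning. Initial values are over-dispersed prior
#' draws (factor \code{initDispersion}); latent states start from the crude
#' data-implied index at the anchor detection value. If compilation or
#' initialisation fails at a dispersed starting point, the dispersion is
#' halved and the fit retried (at most three times) before failing with the
#' sampler's diagnostics. Reproducible given the config seed.
#'
#' @param dataset a \code{\linkS4class{SurveyDataset}} with at least two
#'   years and one observed cell per method.
#' @param priors a \code{\linkS4class{PriorSpec}} (default:
#'   \code{defaultPriors(dataset)}).
#' @param config an \code{\linkS4class{McmcConfig}}.
#' @param beta2 fixed ground baseline logit (identifiability anchor).
#' @param nu fixed Student-t degrees of freedom.
#' @param monitorLatent also monitor \code{logN}, \code{alpha}, \code{delta}
#'   (needed for abundance indices and predictive checks).
#' @param quiet suppress JAGS progress output.
#' @return a \code{\linkS4class{PosteriorSamples}}.
#' @export
fitModel <- function(dataset, priors = defaultPriors(dataset),
                     config = mcmcConfig(), beta2 = 0, nu = 4,
                     monitorLatent = TRUE, quiet = TRUE) {
  stopifnot(is(dataset, "SurveyDataset"), is(priors, "PriorSpec"),
            is(config, "McmcConfig"))
  validObject(config); validObject(priors)
  st <- dataset@structure
  if (st@nYears < 2L) stop("need at least two years of data")
  if (st@nMonths < 2L) stop("need at least two survey months")
  no <- nObserved(dataset)
  if (any(no < 1L))
    stop("need at least one observed cell per method; missing: ",
         paste(names(no)[no < 1L], collapse = ", "))
  design <- buildDetectionDesign(st)
  obs <- observedCells(dataset, design)
  data <- list(S = st@nSites, T = st@nYears, M = st@nMonths, nu = nu,
               beta2 = beta2, J = length(obs$y), y = obs$y, meth = obs$meth,
               month = obs$month, site = obs$site, year = obs$year,
               cell = obs$cell)
  modelStr <- jagsModelString(priors)
  monitors <- c("mu", "sigmaSite", "sigmaYear", "sigmaMonth1", "sigmaMonth2",
                "sigmaObs", "beta1", "gammaA", "gammaG", "p")
  if (monitorLatent) monitors <- c(monitors, "logN", "alpha", "delta")

  dispersion <- config@initDispersion
  jm <- NULL
  for (attempt in 1:3) {
    inits <- lapply(seq_len(config@nChains), function(ch)
      chainInits(dataset, priors, config, ch, dispersion))
    jm <- tryCatch(
      rjags::jags.model(textConnection(modelStr), data = data, inits = inits,
                        n.chains = config@nChains,
                        n.adapt = max(200L, min(1000L, config@nBurnin)),
                        quiet = quiet),
      error = function(e) e)
    if (!inherits(jm, "error")) break
    dispersion <- dispersion / 2
  }
  if (inherits(jm, "error"))
    stop("sampler failed to initialise even with shrunken dispersion: ",
         conditionMessage(jm))

  if (config@nBurnin > 0L)
    stats::update(jm, config@nBurnin, progress.bar = if (quiet) "none" else "text")
  mcl <- rjags::coda.samples(jm, variable.names = monitors,
                             n.iter = config@nIterations - config@nBurnin,
                             thin = config@thin,
                             progress.bar = if (quiet) "none" else "text")

  nIter <- nrow(mcl[[1]])
  pars <- renameDraws(colnames(mcl[[1]]))
  draws <- array(NA_real_, c(nIter, config@nChains, length(pars)),
                 dimnames = list(NULL, NULL, pars))
  for (ch in seq_along(mcl)) draws[, ch, ] <- as.matrix(mcl[[ch]])

  out <- new("PosteriorSamples", draws = draws, config = config,
             structure = st, design = design, beta2 = beta2,
             rhat = numeric(0), ess = numeric(0))
  out@rhat <- rhat(out)
  out@ess <- vapply(seq_along(pars), function(k) {
    v <- as.vector(draws[, , k])
    if (stats::sd(v) == 0) return(NA_real_)
    sum(coda::effectiveSize(coda::as.mcmc.list(
      lapply(seq_len(config@nChains), function(ch) coda::mcmc(draws[, ch, k])))))
  }, numeric(1))
  names(out@ess) <- pars
  out
}

#' Split-chain potential scale reduction factor of one parameter
#'
#' Each chain is split in half; the ratio of pooled to within-half variance
#' gives the Brooks-Gelman-Rubin statistic. Values near 1 indicate the halves
#' agree; the conventional convergence criterion is R-hat < 1.1. For a
#' parameter with zero within-chain variance the statistic is undefined and
#' \code{NA} is returned (a constant is not evidence of convergence).
#'
#' @param mat iterations x chains matrix of draws.
#' @return scalar R-hat (or \code{NA}).
#' @export
splitRhat <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 4L) stop("need at least 4 draws per chain to split")
  half <- n %/% 2L
  halves <- do.call(cbind, lapply(seq_len(ncol(mat)), function(ch)
    cbind(mat[seq_len(half), ch], mat[(n - half + 1L):n, ch])))
  m <- ncol(halves); nh <- nrow(halves)
  W <- mean(apply(halves, 2, stats::var))
  B <- nh * stats::var(colMeans(halves))
  if (!is.finite(W) || W == 0) {
    # constant chains: undefined when all agree; infinite (non-mixing) when
    # chains sit at distinct constants
    return(if (is.finite(B) && B > 0) Inf else NA_real_)
  }
  varPlus <- (nh - 1) / nh * W + B / nh
  sqrt(varPlus / W)
}

#' @rdname rhat
#' @param parameters optional subset of parameter names.
#' @export
setMethod("rhat", "PosteriorSamples", function(object, parameters = NULL) {
  pars <- dimnames(object@draws)[[3]]
  if (!is.null(parameters)) pars <- intersect(parameters, pars)
  out <- vapply(pars, function(k) splitRhat(object@draws[, , k]), numeric(1))
  names(out) <- pars
  out
})

#' @rdname effectiveSamples
#' @export
setMethod("effectiveSamples", "PosteriorSamples", function(object, ...) object@ess)

#' @rdname drawsOf
#' @export
setMethod("drawsOf", "PosteriorSamples", function(object, parameters) {
  pars <- dimnames(object@draws)[[3]]
  bad <- setdiff(parameters, pars)
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  d <- dim(object@draws)
  out <- matrix(object@draws[, , match(parameters, pars)], d[1] * d[2],
                length(parameters))
  colnames(out) <- parameters
  out
})

#' @rdname parameterNames
#' @export
setMethod("parameterNames", "PosteriorSamples", function(object, which = "all") {
  pars <- dimnames(object@draws)[[3]]
  switch(which,
    all = pars,
    top = intersect(kFreeParameters, pars),
    cells = paste0("p_", sub("^(aerial|ground)_", "", cellsPresent(object@design))),
    stop("unknown parameter group: ", which))
})

#' @rdname nSites
#' @export
setMethod("nSites", "PosteriorSamples", function(object) object@structure@nSites)
#' @rdname nSites
#' @export
setMethod("nYears", "PosteriorSamples", function(object) object@structure@nYears)
#' @rdname nSites
#' @export
setMethod("nMonths", "PosteriorSamples", function(object) object@structure@nMonths)
#' @rdname studyStructure
#' @export
setMethod("studyStructure", "PosteriorSamples", function(object) object@structure)

setMethod("show", "PosteriorSamples", function(object) {
  d <- dim(object@draws)
  cfg <- object@config
  top <- parameterNames(object, "top")
  cat(sprintf("PosteriorSamples: %d draws x %d chains x %d parameters\n",
              d[1], d[2], d[3]))
  cat(sprintf("  config: %d iterations, %d burn-in, thin %d (seed %d); beta2 fixed at %g\n",
              cfg@nIterations, cfg@nBurnin, cfg@thin, cfg@seed, object@beta2))
  cat(sprintf("  max split R-hat over top-level parameters: %.3f\n",
              max(object@rhat[top], na.rm = TRUE)))
})
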