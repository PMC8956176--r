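#' @include AllClasses.R simulate.R
NULL

#' Construct a PriorSpec
#'
#' @param entries named list over \code{kFreeParameters}; each element
#'   \code{list(family = "normal"|"halfnormal", pars = c(...))}.
#' @return a validated \code{\linkS4class{PriorSpec}}.
#' @export
priorSpec <- function(entries) new("PriorSpec", entries = entries)

#' Weakly informative default priors
#'
#' The package's documented defaults: Normal(log median observed count + 1,
#' 1.5) for \code{mu} (centred on the data's scale, wide enough to cover two
#' orders of magnitude either way); half-Normal(1) for every SD; Normal(0,
#' 1.5) for the aerial baseline logit and all detection offsets, covering
#' detection indices of roughly (0.05, 0.95). No entry exists for the fixed
#' anchors \code{beta2} and \code{nu}.
#'
#' @param dataset optional \code{\linkS4class{SurveyDataset}} used to centre
#'   the \code{mu} prior; without it the centre falls back to log(300).
#' @return a \code{\linkS4class{PriorSpec}}.
#' @export
defaultPriors <- function(dataset = NULL) {
  muCentre <- if (!is.null(dataset)) {
    med <- stats::median(dataset@counts, na.rm = TRUE)
    log(med + 1)
  } else log(300)
  e <- list()
  e$mu <- list(family = "normal", pars = c(muCentre, 1.5))
  for (nm in c("sigma_site", "sigma_year", "sigma_month1", "sigma_month2",
               "sigma_obs_aerial", "sigma_obs_ground"))
    e[[nm]] <- list(family = "halfnormal", pars = 1)
  for (nm in c("beta1", "gamma_obs2", "gamma_obs3", "gamma_palissade",
               "gamma_rnn", "gamma_tdv_old", "gamma_tdv_new"))
    e[[nm]] <- list(family = "normal", pars = c(0, 1.5))
  priorSpec(e)
}

#' Point-mass priors at given parameter values
#'
#' Degenerate spec used to reduce prior-predictive simulation to the plain
#' generator in tests; represented as vanishingly narrow distributions.
#'
#' @param params a \code{\linkS4class{ModelParameters}}.
#' @param width tiny positive SD/scale standing in for a point mass.
#' @return a \code{\linkS4class{PriorSpec}}.
#' @export
pointMassPriors <- function(params, width = 1e-12) {
  vec <- topLevelVector(params)
  e <- lapply(kFreeParameters, function(nm) {
    list(family = "normal", pars = c(vec[[nm]], width), point = vec[[nm]])
  })
  names(e) <- kFreeParameters
  priorSpec(e)
}

#' Draw top-level parameters from a prior specification
#'
#' Draws outside a parameter's domain (non-positive scales) are rejected and
#' redrawn; the rejection rate is returned as an attribute.
#'
#' @param priors a \code{\linkS4class{PriorSpec}}.
#' @param nu fixed degrees of freedom for the returned parameters.
#' @param beta2 fixed ground baseline logit.
#' @return a \code{\linkS4class{ModelParameters}} (empty latent slots) with
#'   attribute \code{"rejections"}.
#' @export
priorSample <- function(priors, nu = 4, beta2 = 0) {
  rejections <- 0L
  draw1 <- function(nm) {
    e <- priors@entries[[nm]]
    if (!is.null(e$point)) return(e$point)
    positive <- e$family == "halfnormal" || startsWith(nm, "sigma")
    repeat {
      x <- switch(e$family,
        normal = stats::rnorm(1, e$pars[1], e$pars[2]),
        halfnormal = abs(stats::rnorm(1, 0, e$pars[1])))
      if (!positive || x > 0) return(x)
      rejections <<- rejections + 1L
    }
  }
  v <- vapply(kFreeParameters, draw1, numeric(1))
  out <- modelParameters(
    mu = v[["mu"]], sigmaSite = v[["sigma_site"]],
    sigmaYear = v[["sigma_year"]], sigmaMonth1 = v[["sigma_month1"]],
    sigmaMonth2 = v[["sigma_month2"]],
    sigmaObs = c(aerial = v[["sigma_obs_aerial"]],
                 ground = v[["sigma_obs_ground"]]),
    nu = nu, beta1 = v[["beta1"]], beta2 = beta2,
    gammaAerial = c(obs2 = v[["gamma_obs2"]], obs3 = v[["gamma_obs3"]]),
    gammaGround = c(palissade = v[["gamma_palissade"]],
                    rnn = v[["gamma_rnn"]],
                    tdv_old = v[["gamma_tdv_old"]],
                    tdv_new = v[["gamma_tdv_new"]]))
  attr(out, "rejections") <- rejections
  out
}

#' Prior predictive simulation
#'
#' Each draw samples top-level parameters from the priors and runs the
#' synthetic-data generators at them, giving datasets whose spread reflects
#' prior uncertainty; used to check that the priors imply plausible count
#' magnitudes before seeing data.
#'
#' @param priors a \code{\linkS4class{PriorSpec}}.
#' @param structure a \code{\linkS4class{StudyStructure}}.
#' @param nDraws number of prior draws (>= 1).
#' @param seed integer seed.
#' @return list with \code{datasets} (list of
#'   \code{\linkS4class{SurveyDataset}}), \code{parameters} (the prior
#'   draws), \code{countQuantiles} (1/25/50/75/99\% quantiles of all
#'   simulated observed counts) and \code{rejectionRate} of domain redraws.
#' @export
priorPredictive <- function(priors, structure, nDraws, seed) {
  if (!is.numeric(nDraws) || nDraws < 1L) stop("nDraws must be >= 1")
  datasets <- vector("list", nDraws)
  parameters <- vector("list", nDraws)
  rej <- 0L
  for (d in seq_len(nDraws)) {
    set.seed(splitSeed(seed, 100L + d))
    pars <- priorSample(priors)
    rej <- rej + attr(pars, "rejections")
    sim <- simulateSurvey(list(structure = structure, parameters = pars,
                               seed = splitSeed(seed, 200L + d)))
    parameters[[d]] <- pars
    datasets[[d]] <- sim$dataset
  }
  allCounts <- unlist(lapply(datasets, function(d) d@counts[!is.na(d@counts)]))
  list(datasets = datasets, parameters = parameters,
       countQuantiles = stats::quantile(allCounts,
                                        c(0.01, 0.25, 0.5, 0.75, 0.99)),
       rejectionRate = rej / (rej + nDraws * length(kFreeParameters)))
}
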