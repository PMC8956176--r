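#' @include AllClasses.R
NULL

#' Construct a ModelParameters object
#'
#' Top-level parameters are required; latent states (\code{r}, \code{delta},
#' \code{alpha}, \code{logN1}) may be left empty and are filled in by
#' \code{\link{generateTruth}}.
#'
#' @param mu expected initial log abundance.
#' @param sigmaSite,sigmaYear,sigmaMonth1,sigmaMonth2 positive scale
#'   parameters (see \code{\linkS4class{ModelParameters}}).
#' @param sigmaObs length-2 observation scales, order (aerial, ground).
#' @param nu Student-t degrees of freedom (fixed; default 4).
#' @param beta1 aerial baseline logit.
#' @param beta2 ground baseline logit (identifiability anchor, default 0).
#' @param gammaAerial length-2 offsets (observer 2, observer 3).
#' @param gammaGround length-4 offsets (Palissade, RNN Camargue, Tour du
#'   Valat old, Tour du Valat new).
#' @param r,delta,alpha,logN1 optional latent states.
#' @return a validated \code{\linkS4class{ModelParameters}}.
#' @export
modelParameters <- function(mu, sigmaSite, sigmaYear, sigmaMonth1, sigmaMonth2,
                            sigmaObs, nu = 4, beta1 = 0, beta2 = 0,
                            gammaAerial = c(obs2 = 0, obs3 = 0),
                            gammaGround = c(palissade = 0, rnn = 0,
                                            tdv_old = 0, tdv_new = 0),
                            r = matrix(numeric(0), 0, 0), delta = numeric(0),
                            alpha = matrix(numeric(0), 0, 0),
                            logN1 = numeric(0)) {
  for (nm in c("sigmaSite", "sigmaYear", "sigmaMonth1", "sigmaMonth2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("non-positive scale parameter: ", nm)
  }
  if (any(sigmaObs <= 0)) stop("non-positive scale parameter: sigmaObs")
  sigmaObs <- stats::setNames(as.numeric(sigmaObs), kMethods)
  names(gammaAerial) <- c("obs2", "obs3")
  names(gammaGround) <- c("palissade", "rnn", "tdv_old", "tdv_new")
  new("ModelParameters", mu = mu, sigmaSite = sigmaSite, sigmaYear = sigmaYear,
      sigmaMonth1 = sigmaMonth1, sigmaMonth2 = sigmaMonth2,
      sigmaObs = sigmaObs, nu = nu, beta1 = beta1, beta2 = beta2,
      gammaAerial = gammaAerial, gammaGround = gammaGround,
      r = r, delta = delta, alpha = alpha, logN1 = logN1)
}

#' Default generating parameters for the synthetic fixtures
#'
#' One fixed set of ecologically plausible values used by all fixtures:
#' initial site abundances around 300 birds (a typical Camargue day-roost
#' holds hundreds to a few thousand wintering ducks or coots), moderate
#' between-site spread, slow year-to-year drift of growth rates, a seasonal
#' random walk producing a bell-shaped within-winter pattern, heavier aerial
#' than ground observation noise, and detection logits making the aerial
#' baseline observer detect fewer birds than the anchored ground cell, with
#' the third aerial observer and the flushing ground protocols detecting
#' most.
#'
#' @return a \code{\linkS4class{ModelParameters}} with empty latent states.
#' @export
fixtureParameters <- function() {
  modelParameters(
    mu = log(300), sigmaSite = 0.8, sigmaYear = 0.12,
    sigmaMonth1 = 0.25, sigmaMonth2 = 0.12,
    sigmaObs = c(aerial = 0.35, ground = 0.25), nu = 4,
    beta1 = -0.45, beta2 = 0,
    gammaAerial = c(obs2 = 0.10, obs3 = 0.65),
    gammaGround = c(palissade = 0.35, rnn = -0.20,
                    tdv_old = -0.15, tdv_new = 0.45))
}

#' Named top-level parameter vector
#'
#' Flattens the free top-level parameters into the naming scheme used by
#' priors and posterior draws (\code{kFreeParameters}).
#'
#' @param params a \code{\linkS4class{ModelParameters}}.
#' @return named numeric vector.
#' @export
topLevelVector <- function(params) {
  c(mu = params@mu, sigma_site = params@sigmaSite,
    sigma_year = params@sigmaYear, sigma_month1 = params@sigmaMonth1,
    sigma_month2 = params@sigmaMonth2,
    sigma_obs_aerial = unname(params@sigmaObs["aerial"]),
    sigma_obs_ground = unname(params@sigmaObs["ground"]),
    beta1 = params@beta1,
    gamma_obs2 = unname(params@gammaAerial["obs2"]),
    gamma_obs3 = unname(params@gammaAerial["obs3"]),
    gamma_palissade = unname(params@gammaGround["palissade"]),
    gamma_rnn = unname(params@gammaGround["rnn"]),
    gamma_tdv_old = unname(params@gammaGround["tdv_old"]),
    gamma_tdv_new = unname(params@gammaGround["tdv_new"]))
}

#' Serialize model parameters to JSON
#'
#' @param params a \code{\linkS4class{ModelParameters}}.
#' @param path file to write; the JSON carries named fields matching the
#'   model symbols, including any latent states present.
#' @return \code{path}, invisibly.
#' @export
writeParameters <- function(params, path) {
  obj <- list(
    mu = params@mu, sigma_site = params@sigmaSite,
    sigma_year = params@sigmaYear, sigma_month1 = params@sigmaMonth1,
    sigma_month2 = params@sigmaMonth2, sigma_obs = as.list(params@sigmaObs),
    nu = params@nu, beta1 = params@beta1, beta2 = params@beta2,
    gamma_aerial = as.list(params@gammaAerial),
    gamma_ground = as.list(params@gammaGround))
  if (length(params@logN1)) obj$logN1 <- params@logN1
  if (length(params@r)) obj$r <- params@r
  if (length(params@delta)) obj$delta <- params@delta
  if (length(params@alpha)) obj$alpha <- params@alpha
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

setMethod("show", "ModelParameters", function(object) {
  cat("ModelParameters\n")
  cat(sprintf("  mu = %.3f, sigma_site = %.3f, sigma_year = %.3f\n",
              object@mu, object@sigmaSite, object@sigmaYear))
  cat(sprintf("  seasonal SDs = (%.3f, %.3f); sigma_obs = (%.3f aerial, %.3f ground); nu = %g\n",
              object@sigmaMonth1, object@sigmaMonth2,
              object@sigmaObs["aerial"], object@sigmaObs["ground"], object@nu))
  cat(sprintf("  beta1 = %.3f, beta2 = %.3f (fixed)\n", object@beta1, object@beta2))
  cat("  gamma (aerial):", paste(sprintf("%s = %.3f", names(object@gammaAerial),
                                         object@gammaAerial), collapse = ", "), "\n")
  cat("  gamma (ground):", paste(sprintf("%s = %.3f", names(object@gammaGround),
                                         object@gammaGround), collapse = ", "), "\n")
  if (length(object@logN1))
    cat(sprintf("  latent states present for %d sites\n", length(object@logN1)))
})
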