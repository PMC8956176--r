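#' @include AllClasses.R mcmc.R
NULL

#' Exceedance probability between two sets of draws
#'
#' Fraction of \code{samplesA} lying above the upper 95\% credible limit
#' (97.5\% quantile) of \code{samplesB}: the device used to compare detection
#' cells pairwise ("probability that cell a detects more than cell b").
#'
#' @param samplesA,samplesB non-empty numeric draw vectors.
#' @return probability in [0, 1].
#' @export
exceedanceProbability <- function(samplesA, samplesB) {
  if (!length(samplesA) || !length(samplesB)) stop("empty draw set")
  upper <- stats::quantile(samplesB, 0.975, names = FALSE)
  mean(samplesA > upper)
}

#' Posterior ratio of two detection cells
#'
#' Per-draw ratio \code{pA / pB} (draws paired per MCMC iteration) summarised
#' by mean and SD: the "times more individuals detected" comparison, since
#' expected counts scale multiplicatively with the detection index.
#'
#' @param samplesA,samplesB paired draw vectors of equal length.
#' @return list with \code{mean}, \code{sd} and the per-draw \code{ratios}.
#' @export
detectionRatio <- function(samplesA, samplesB) {
  if (length(samplesA) != length(samplesB))
    stop("draw vectors must be paired per iteration (equal lengths)")
  if (!length(samplesA)) stop("empty draw set")
  ratios <- samplesA / samplesB
  list(mean = mean(ratios), sd = stats::sd(ratios), ratios = ratios)
}

#' Posterior summaries of the detection cells
#'
#' Per cell present in the fitted design: posterior mean, SD and equal-tailed
#' 95\% credible interval of the detection index, plus matrices of pairwise
#' posterior ratios and exceedance probabilities.
#'
#' @param samples a \code{\linkS4class{PosteriorSamples}}.
#' @return a \code{\linkS4class{DetectionSummary}}.
#' @export
detectionSummary <- function(samples) {
  cells <- parameterNames(samples, "cells")
  draws <- drawsOf(samples, cells)
  q <- apply(draws, 2, stats::quantile, c(0.025, 0.975))
  tb <- data.frame(cell = cells, mean = colMeans(draws),
                   sd = apply(draws, 2, stats::sd),
                   lower = q[1, ], upper = q[2, ], row.names = NULL)
  K <- length(cells)
  rm <- rs <- ex <- matrix(NA_real_, K, K, dimnames = list(cells, cells))
  for (a in seq_len(K)) for (b in seq_len(K)) {
    dr <- detectionRatio(draws[, a], draws[, b])
    rm[a, b] <- dr$mean; rs[a, b] <- dr$sd
    ex[a, b] <- exceedanceProbability(draws[, a], draws[, b])
  }
  new("DetectionSummary", table = tb, ratioMean = rm, ratioSD = rs,
      exceedance = ex, pDraws = draws)
}

setMethod("show", "DetectionSummary", function(object) {
  cat("DetectionSummary (conditional detection indices)\n")
  tb <- object@table
  for (k in seq_len(nrow(tb)))
    cat(sprintf("  %-18s %.3f +/- %.3f  [%.3f, %.3f]\n", tb$cell[k],
                tb$mean[k], tb$sd[k], tb$lower[k], tb$upper[k]))
})

#' Posterior abundance-index series
#'
#' Summarises \code{exp(log N[s,t] + alpha[m,t])} draws for the chosen month:
#' posterior mean and equal-tailed 95\% credible interval per site and year,
#' or per protected area (the area index is the per-draw sum over member
#' sites, then summarised). With the September anchor (\code{month = 1},
#' \code{delta[1] = 0}) the site series summarises \code{N[s,t]} up to the
#' year's seasonal deviation.
#'
#' @param samples a \code{\linkS4class{PosteriorSamples}} fitted with latent
#'   monitoring.
#' @param month month index, 1 = September (5 = January).
#' @param level \code{"site"} or \code{"area"}.
#' @return an \code{\linkS4class{AbundanceIndexSeries}}.
#' @export
abundanceIndex <- function(samples, month, level = c("site", "area")) {
  level <- match.arg(level)
  st <- samples@structure
  if (!is.numeric(month) || length(month) != 1L || month < 1L ||
      month > st@nMonths)
    stop("month out of range: must be in 1..", st@nMonths)
  S <- st@nSites; T <- st@nYears
  alphaDraws <- drawsOf(samples, sprintf("alpha[%d,%d]", month, seq_len(T)))
  idx <- array(NA_real_, c(nrow(alphaDraws), S, T))
  for (s in seq_len(S)) {
    ln <- drawsOf(samples, sprintf("logN[%d,%d]", s, seq_len(T)))
    idx[, s, ] <- exp(ln + alphaDraws)
  }
  if (level == "area") {
    areas <- sort(unique(st@areaOfSite))
    agg <- array(NA_real_, c(nrow(alphaDraws), length(areas), T))
    for (a in seq_along(areas)) {
      sites <- which(st@areaOfSite == areas[a])
      agg[, a, ] <- apply(idx[, sites, , drop = FALSE], c(1, 3), sum)
    }
    idx <- agg
    units <- areas
  } else units <- as.character(seq_len(S))

  mean_ <- apply(idx, c(2, 3), mean)
  lo <- apply(idx, c(2, 3), stats::quantile, 0.025)
  hi <- apply(idx, c(2, 3), stats::quantile, 0.975)
  tb <- data.frame(
    level = level,
    unit = rep(units, times = T),
    year = rep(seq_len(T), each = length(units)),
    month = as.integer(month),
    mean = as.vector(mean_), lower = as.vector(lo), upper = as.vector(hi))
  new("AbundanceIndexSeries", table = tb, month = as.integer(month),
      level = level, indexDraws = idx)
}

setMethod("show", "AbundanceIndexSeries", function(object) {
  cat(sprintf("AbundanceIndexSeries (%s level, month %d): %d rows\n",
              object@level, object@month, nrow(object@table)))
})

#' Rank correlation between the abundance index and observed counts
#'
#' Spearman correlation between the posterior-mean site-level index and the
#' observed counts of one method at the series' month, over cells observed in
#' the data.
#'
#' @param index a site-level \code{\linkS4class{AbundanceIndexSeries}}.
#' @param dataset the fitted \code{\linkS4class{SurveyDataset}}.
#' @param method \code{"aerial"} or \code{"ground"}.
#' @return Spearman's rho.
#' @export
correlateWithCounts <- function(index, dataset, method) {
  if (!method %in% kMethods) stop("unknown method: ", method)
  if (index@level != "site") stop("need a site-level index series")
  st <- dataset@structure
  i <- match(method, kMethods)
  tb <- index@table
  obs <- dataset@counts[cbind(i, index@month, as.integer(tb$unit), tb$year)]
  keep <- !is.na(obs)
  if (sum(keep) < 3L) stop("fewer than 3 overlapping observed cells")
  stats::cor(tb$mean[keep], obs[keep], method = "spearman")
}

#' Sensitivity of detection contrasts to the fixed baseline
#'
#' Refits the model once per candidate value of the fixed ground baseline
#' logit \code{beta2} and reports, per baseline, the detection summaries and
#' the matrix of pairwise logit-scale cell differences (posterior mean and
#' 95\% interval). Because only contrasts to the anchor are identified,
#' shifting the anchor should shift every cell by a constant and leave the
#' differences unchanged: the check that anchoring does not bias detection
#' contrasts.
#'
#' @param dataset a \code{\linkS4class{SurveyDataset}}.
#' @param priors a \code{\linkS4class{PriorSpec}}.
#' @param config an \code{\linkS4class{McmcConfig}}.
#' @param baselines non-empty numeric vector of fixed \code{beta2} values.
#' @param quiet passed to \code{\link{fitModel}}.
#' @return list with one element per baseline: \code{list(beta2, fit,
#'   summary, logitDiff)} where \code{logitDiff} is a list of \code{mean},
#'   \code{lower}, \code{upper} matrices of pairwise logit differences.
#' @export
sensitivityScan <- function(dataset, priors = defaultPriors(dataset),
                            config = mcmcConfig(), baselines, quiet = TRUE) {
  if (!length(baselines)) stop("baselines must be non-empty")
  lapply(baselines, function(b2) {
    fit <- tryCatch(
      fitModel(dataset, priors, config, beta2 = b2, quiet = quiet),
      error = function(e) stop("fit failed at baseline ", b2, ": ",
                               conditionMessage(e)))
    ds <- detectionSummary(fit)
    cells <- colnames(ds@pDraws)
    lg <- stats::qlogis(ds@pDraws)
    K <- length(cells)
    dm <- dl <- du <- matrix(NA_real_, K, K, dimnames = list(cells, cells))
    for (a in seq_len(K)) for (b in seq_len(K)) {
      d <- lg[, a] - lg[, b]
      dm[a, b] <- mean(d)
      dl[a, b] <- stats::quantile(d, 0.025)
      du[a, b] <- stats::quantile(d, 0.975)
    }
    list(beta2 = b2, fit = fit, summary = ds,
         logitDiff = list(mean = dm, lower = dl, upper = du))
  })
}

#' Posterior predictive fit check
#'
#' For a subsample of retained draws, simulates replicated log-scale
#' observations from the observation model at that draw's latent states and
#' parameters and compares discrepancy statistics (per-method mean, SD and
#' maximum of the transformed counts) between replicated and observed data.
#' Reports posterior-predictive p-values \code{P(T_rep >= T_obs)} per method
#' and statistic, and the share of observed cells inside their central 95\%
#' predictive interval. Extreme p-values (near 0 or 1) flag systematic
#' misfit; the per-method maximum is sensitive to outlier blocks.
#'
#' The replicated generation reuses the generator's own noise code, so a
#' point-mass posterior with a matching seed reproduces
#' \code{\link{generateCounts}} draw for draw.
#'
#' @param samples a \code{\linkS4class{PosteriorSamples}} with latent
#'   monitoring.
#' @param dataset the fitted \code{\linkS4class{SurveyDataset}}.
#' @param seed integer seed for the replicate streams.
#' @param nDraws number of posterior draws to use (subsampled evenly).
#' @return list with \code{pvalues} (methods x statistics matrix),
#'   \code{coverage95} (named per method), \code{observed} and
#'   \code{replicated} statistic arrays.
#' @export
posteriorFitCheck <- function(samples, dataset, seed, nDraws = 200L) {
  st <- samples@structure
  S <- st@nSites; T <- st@nYears; M <- st@nMonths
  y <- dataset@logCounts
  if (!identical(dim(y), c(2L, M, S, T)))
    stop("dataset does not match the fitted structure")
  total <- dim(samples@draws)[1] * dim(samples@draws)[2]
  nDraws <- min(nDraws, total)
  pick <- unique(round(seq(1, total, length.out = nDraws)))

  lnNames <- as.vector(outer(seq_len(S), seq_len(T),
                             function(s, t) sprintf("logN[%d,%d]", s, t)))
  alNames <- as.vector(outer(seq_len(M), seq_len(T),
                             function(m, t) sprintf("alpha[%d,%d]", m, t)))
  cellNames <- paste0("p_", sub("^(aerial|ground)_", "", kDetectionCells))
  have <- dimnames(samples@draws)[[3]]
  lnD <- drawsOf(samples, lnNames)[pick, , drop = FALSE]
  alD <- drawsOf(samples, alNames)[pick, , drop = FALSE]
  pD <- drawsOf(samples, intersect(cellNames, have))[pick, , drop = FALSE]
  soD <- drawsOf(samples, c("sigma_obs_aerial", "sigma_obs_ground"))[pick, , drop = FALSE]

  stat3 <- function(v) c(mean = mean(v), sd = stats::sd(v), max = max(v))
  obsMask <- !is.na(y)
  obsStat <- rbind(aerial = stat3(y[1, , , ][obsMask[1, , , ]]),
                   ground = stat3(y[2, , , ][obsMask[2, , , ]]))

  nd <- length(pick)
  repStat <- array(NA_real_, c(nd, 2, 3),
                   dimnames = list(NULL, kMethods, c("mean", "sd", "max")))
  inside <- array(0L, dim(y))
  lowQ <- array(NA_real_, c(nd, sum(obsMask)))
  cellArr <- samples@design@cells
  pIndex <- match(paste0("p_", sub("^(aerial|ground)_", "", cellArr)),
                  colnames(pD))
  for (d in seq_len(nd)) {
    logN <- matrix(lnD[d, ], S, T)
    alpha <- matrix(alD[d, ], M, T)
    pArr <- array(pD[d, pIndex], dim(cellArr))
    yRep <- drawLogObservations(logN, alpha, pArr,
                                c(soD[d, 1], soD[d, 2]), 4,
                                splitSeed(seed, d))
    for (i in 1:2)
      repStat[d, i, ] <- stat3(yRep[i, , , ][obsMask[i, , , ]])
    lowQ[d, ] <- yRep[obsMask]
  }
  pv <- matrix(NA_real_, 2, 3, dimnames = list(kMethods, c("mean", "sd", "max")))
  for (i in 1:2) for (k in 1:3)
    pv[i, k] <- mean(repStat[, i, k] >= obsStat[i, k])
  qs <- apply(lowQ, 2, stats::quantile, c(0.025, 0.975))
  yObs <- y[obsMask]
  inCover <- yObs >= qs[1, ] & yObs <= qs[2, ]
  methOfObs <- slice.index(y, 1)[obsMask]
  coverage <- c(aerial = mean(inCover[methOfObs == 1]),
                ground = mean(inCover[methOfObs == 2]))
  list(pvalues = pv, coverage95 = coverage, observed = obsStat,
       replicated = repStat)
}

#' Prior-posterior overlap of the top-level parameters
#'
#' For each free parameter, compares the posterior spread to the prior spread
#' (SD ratio) and the share of posterior draws inside the central 95\% prior
#' interval. Parameters whose data contribute no information (for instance
#' detection offsets with no anchored contrast) keep a posterior close to
#' the prior: SD ratio near 1, prior-interval share near 0.95.
#'
#' @param samples a \code{\linkS4class{PosteriorSamples}}.
#' @param priors the \code{\linkS4class{PriorSpec}} used in the fit.
#' @param sdRatioFlag SD ratio above which a parameter is flagged near-prior.
#' @return data.frame with columns parameter, sdRatio, priorMass, nearPrior.
#' @export
priorPosteriorOverlap <- function(samples, priors, sdRatioFlag = 0.75) {
  pars <- parameterNames(samples, "top")
  rows <- lapply(pars, function(nm) {
    e <- priors@entries[[nm]]
    dr <- drawsOf(samples, nm)[, 1]
    priorSD <- switch(e$family, normal = e$pars[2],
                      halfnormal = e$pars[1] * sqrt(1 - 2 / pi))
    priorInt <- switch(e$family,
      normal = stats::qnorm(c(0.025, 0.975), e$pars[1], e$pars[2]),
      halfnormal = e$pars[1] * stats::qnorm(c(0.5125, 0.9875)))
    data.frame(parameter = nm, sdRatio = stats::sd(dr) / priorSD,
               priorMass = mean(dr >= priorInt[1] & dr <= priorInt[2]))
  })
  out <- do.call(rbind, rows)
  out$nearPrior <- out$sdRatio > sdRatioFlag
  out
}
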