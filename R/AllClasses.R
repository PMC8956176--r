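#' @import methods
NULL

#' Canonical labels used by the detection design
#'
#' The logit-linear detection model distinguishes eight cells: three aerial
#' observer periods, four estimated ground protected-area cells (the Tour du
#' Valat contributes two, before and after its protocol change), and the fixed
#' ground anchor cell (Marais du Vigueirat), whose linear predictor is exactly
#' the ground baseline logit.
#'
#' @format Character vectors of cell and area labels.
#' @name designLabels
NULL

#' @rdname designLabels
#' @export
kDetectionCells <- c(
  "aerial_obs1", "aerial_obs2", "aerial_obs3",
  "ground_palissade", "ground_rnn", "ground_tdv_old", "ground_tdv_new",
  "ground_vigueirat"
)

#' @rdname designLabels
#' @export
kAreas <- c("Palissade", "RNNCamargue", "TourDuValat", "Vigueirat")

#' @rdname designLabels
#' @export
kMethods <- c("aerial", "ground")

#' StudyStructure: the observational design of a dual-protocol survey
#'
#' Encodes everything about the survey layout that is not a model parameter:
#' how many sites, years and months are monitored, which protected area each
#' site belongs to, which aerial observer covered each year, when (if ever) a
#' ground protocol change occurred within an area, from which year each site
#' was covered by the aerial survey, and the per-(method, area) missingness
#' rates used by the synthetic-data generator.
#'
#' @slot nSites number of monitored sites (wetland polygons).
#' @slot nYears number of study years; year 1 is the first analysed winter.
#' @slot nMonths number of survey months per winter; month 1 is September.
#' @slot areaOfSite character vector, length \code{nSites}; one of
#'   \code{kAreas} per site.
#' @slot observerPeriodOfYear integer vector, length \code{nYears}, values in
#'   \{1, 2, 3\}; contiguous blocks mapping years to aerial observers.
#' @slot changeArea area label affected by a ground protocol change, or
#'   character(0) when no change occurred.
#' @slot changeYear first year under the new ground protocol (integer(0) when
#'   no change occurred).
#' @slot aerialIntroYear integer vector, length \code{nSites}: first year each
#'   site was covered by the aerial survey (1 = from the start).
#' @slot missingnessRate numeric matrix, methods x areas, fractions in [0, 1].
#' @export
setClass("StudyStructure", representation(
  nSites = "integer",
  nYears = "integer",
  nMonths = "integer",
  areaOfSite = "character",
  observerPeriodOfYear = "integer",
  changeArea = "character",
  changeYear = "integer",
  aerialIntroYear = "integer",
  missingnessRate = "matrix"
))

setValidity("StudyStructure", function(object) {
  msg <- character(0)
  S <- object@nSites; T <- object@nYears; M <- object@nMonths
  if (S < 1L || T < 2L || M < 1L)
    msg <- c(msg, "need nSites >= 1, nYears >= 2, nMonths >= 1")
  if (length(object@areaOfSite) != S)
    msg <- c(msg, "areaOfSite must have one entry per site")
  if (!all(object@areaOfSite %in% kAreas))
    msg <- c(msg, sprintf("unknown area label(s): %s",
                          paste(setdiff(object@areaOfSite, kAreas), collapse = ", ")))
  per <- object@observerPeriodOfYear
  if (length(per) != T) {
    msg <- c(msg, "observerPeriodOfYear must have one entry per year")
  } else {
    if (!all(per %in% 1:3))
      msg <- c(msg, "observer periods must be coded 1, 2 or 3")
    if (any(diff(per) < 0) || any(diff(per) > 1))
      msg <- c(msg, "observer periods must form contiguous non-decreasing blocks")
    if (per[1] != 1L)
      msg <- c(msg, "the first year must belong to observer period 1")
  }
  if (length(object@changeArea) != length(object@changeYear))
    msg <- c(msg, "changeArea and changeYear must both be present or both absent")
  if (length(object@changeArea) == 1L) {
    if (!(object@changeArea %in% object@areaOfSite))
      msg <- c(msg, "ground method change refers to an area with no sites")
    if (object@changeYear < 2L || object@changeYear > T)
      msg <- c(msg, "ground method change year out of range")
  }
  if (length(object@aerialIntroYear) != S ||
      any(object@aerialIntroYear < 1L) || any(object@aerialIntroYear > T))
    msg <- c(msg, "aerialIntroYear must map every site to a year in range")
  mr <- object@missingnessRate
  if (!identical(rownames(mr), kMethods) ||
      !all(colnames(mr) %in% kAreas) ||
      any(mr < 0) || any(mr > 1))
    msg <- c(msg, "missingnessRate must be a methods x areas matrix of fractions in [0, 1]")
  if (!all(object@areaOfSite %in% colnames(mr)))
    msg <- c(msg, "missingnessRate lacks a column for some occupied area")
  if (length(msg)) msg else TRUE
})

#' ModelParameters: every symbol of the state-space model
#'
#' Holds the top-level parameters (initial-state mean and spread, growth-rate
#' innovation SD, seasonal random-walk SDs, per-method observation scales,
#' Student-t degrees of freedom, detection logits) and, when filled in by the
#' generator or an estimator, the latent states (site growth rates, month
#' effects, seasonal offsets, initial log abundances).
#'
#' Identifiability anchors: \code{beta2} (ground baseline logit) and
#' \code{delta[1]} (September month effect) are fixed, not estimated.
#'
#' @slot mu expected initial log abundance (log individuals).
#' @slot sigmaSite SD of initial log abundance among sites.
#' @slot sigmaYear SD of growth-rate innovations (per year).
#' @slot sigmaMonth1 SD of the month-to-month random walk in \code{delta}.
#' @slot sigmaMonth2 SD of interannual seasonal deviations.
#' @slot sigmaObs named numeric length 2 (aerial, ground) observation scales.
#' @slot nu Student-t degrees of freedom of the observation error (fixed).
#' @slot beta1 aerial baseline logit (conditional detection of observer 1).
#' @slot beta2 ground baseline logit, fixed by convention (default 0).
#' @slot gammaAerial named numeric length 2: logit offsets for observers 2, 3.
#' @slot gammaGround named numeric length 4: logit offsets for Palissade,
#'   RNN Camargue, Tour du Valat (old protocol), Tour du Valat (new protocol).
#' @slot r sites x years matrix of growth rates (possibly empty).
#' @slot delta month effects, \code{delta[1] == 0} (possibly empty).
#' @slot alpha months x years matrix of seasonal offsets (possibly empty).
#' @slot logN1 initial log abundance per site (possibly empty).
#' @export
setClass("ModelParameters", representation(
  mu = "numeric",
  sigmaSite = "numeric",
  sigmaYear = "numeric",
  sigmaMonth1 = "numeric",
  sigmaMonth2 = "numeric",
  sigmaObs = "numeric",
  nu = "numeric",
  beta1 = "numeric",
  beta2 = "numeric",
  gammaAerial = "numeric",
  gammaGround = "numeric",
  r = "matrix",
  delta = "numeric",
  alpha = "matrix",
  logN1 = "numeric"
))

setValidity("ModelParameters", function(object) {
  msg <- character(0)
  for (nm in c("sigmaSite", "sigmaYear", "sigmaMonth1", "sigmaMonth2")) {
    v <- slot(object, nm)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("%s must be a single positive number", nm))
  }
  if (length(object@sigmaObs) != 2L || any(object@sigmaObs <= 0) ||
      !identical(names(object@sigmaObs), kMethods))
    msg <- c(msg, "sigmaObs must be positive and named (aerial, ground)")
  if (object@nu <= 0) msg <- c(msg, "nu must be positive")
  if (length(object@gammaAerial) != 2L)
    msg <- c(msg, "gammaAerial must hold offsets for observers 2 and 3")
  if (length(object@gammaGround) != 4L)
    msg <- c(msg, "gammaGround must hold four protected-area offsets")
  if (length(object@delta) && object@delta[1] != 0)
    msg <- c(msg, "delta[1] (September month effect) must be 0: identifiability anchor")
  if (length(object@logN1) && length(object@r) &&
      nrow(object@r) != length(object@logN1))
    msg <- c(msg, "r and logN1 disagree on the number of sites")
  if (length(msg)) msg else TRUE
})

#' SurveyDataset: indexed counts with a missingness mask
#'
#' Counts are stored as a 4-d array indexed (method, month, site, year) with
#' \code{NA} marking missing survey occasions; \code{logCounts} holds the
#' log-transformed observations \code{log(count + 1)} actually entering the
#' likelihood (the generator may carry the exact continuous draws instead, see
#' \code{\link{generateCounts}}).
#'
#' @slot species species label the counts refer to.
#' @slot counts integer array, 2 x months x sites x years, NA = missing.
#' @slot logCounts numeric array of the same shape, log-scale observations.
#' @slot structure the \code{\linkS4class{StudyStructure}} the data follow.
#' @export
setClass("SurveyDataset", representation(
  species = "character",
  counts = "array",
  logCounts = "array",
  structure = "StudyStructure"
))

setValidity("SurveyDataset", function(object) {
  msg <- character(0)
  st <- object@structure
  want <- c(2L, st@nMonths, st@nSites, st@nYears)
  if (!identical(dim(object@counts), want))
    msg <- c(msg, "counts array does not match the study structure dimensions")
  if (!identical(dim(object@logCounts), want))
    msg <- c(msg, "logCounts array does not match the study structure dimensions")
  cnt <- object@counts
  if (any(!is.na(cnt) & (cnt < 0 | cnt != round(cnt))))
    msg <- c(msg, "counts must be non-negative integers where present")
  if (!identical(is.na(object@counts), is.na(object@logCounts)))
    msg <- c(msg, "counts and logCounts disagree on which cells are missing")
  if (length(msg)) msg else TRUE
})

#' DetectionDesign: map from (method, site, year) to a detection cell
#'
#' Aerial cells depend only on the year (through the observer period), never
#' on the site; ground cells depend only on the site's protected area, except
#' the change area (Tour du Valat), which switches cell at the configured
#' protocol-change year. The fixed anchor cell contributes a linear predictor
#' of exactly the ground baseline logit.
#'
#' @slot cells character array, 2 x sites x years, values in
#'   \code{kDetectionCells}.
#' @slot structure the structure the design was built from.
#' @export
setClass("DetectionDesign", representation(
  cells = "array",
  structure = "StudyStructure"
))

setValidity("DetectionDesign", function(object) {
  st <- object@structure
  if (!identical(dim(object@cells), c(2L, st@nSites, st@nYears)))
    return("cells array does not match the study structure")
  if (!all(object@cells %in% kDetectionCells))
    return("unknown detection cell label")
  TRUE
})

#' PriorSpec: one prior per free top-level parameter
#'
#' Each entry names a distribution family (\code{"normal"} or
#' \code{"halfnormal"}) with its hyperparameters. The fixed quantities
#' (\code{beta2}, \code{nu}, \code{delta[1]}) have no entry.
#'
#' @slot entries named list; each element is
#'   \code{list(family = , pars = c(...))}.
#' @export
setClass("PriorSpec", representation(entries = "list"))

setValidity("PriorSpec", function(object) {
  msg <- character(0)
  need <- kFreeParameters
  have <- names(object@entries)
  if (!setequal(have, need) || anyDuplicated(have))
    msg <- c(msg, sprintf(
      "priors must cover each free parameter exactly once; missing: %s; extra: %s",
      paste(setdiff(need, have), collapse = ", "),
      paste(setdiff(have, need), collapse = ", ")))
  for (nm in intersect(have, need)) {
    e <- object@entries[[nm]]
    if (!is.list(e) || is.null(e$family) ||
        !e$family %in% c("normal", "halfnormal"))
      msg <- c(msg, sprintf("%s: unsupported prior family", nm))
    else if (e$family == "normal" &&
             (length(e$pars) != 2L || !is.finite(e$pars[2]) || e$pars[2] <= 0))
      msg <- c(msg, sprintf("%s: normal prior needs (mean, sd > 0)", nm))
    else if (e$family == "halfnormal" &&
             (length(e$pars) != 1L || !is.finite(e$pars[1]) || e$pars[1] <= 0))
      msg <- c(msg, sprintf("%s: half-normal prior needs a positive scale", nm))
  }
  if (length(msg)) msg else TRUE
})

#' Free top-level parameters of the model
#'
#' Every parameter sampled by the MCMC (the fixed anchors \code{beta2},
#' \code{nu} and \code{delta[1]} are excluded).
#' @export
kFreeParameters <- c(
  "mu", "sigma_site", "sigma_year", "sigma_month1", "sigma_month2",
  "sigma_obs_aerial", "sigma_obs_ground", "beta1",
  "gamma_obs2", "gamma_obs3",
  "gamma_palissade", "gamma_rnn", "gamma_tdv_old", "gamma_tdv_new"
)

#' McmcConfig: chain configuration
#'
#' \code{nIterations} counts post-adaptation iterations per chain including
#' burn-in, so each chain retains \code{(nIterations - nBurnin) / thin} draws.
#'
#' @slot nIterations total iterations per chain (after adaptation).
#' @slot nBurnin discarded initial iterations per chain.
#' @slot thin keep every \code{thin}-th sample.
#' @slot nChains number of chains (>= 2 for convergence diagnostics).
#' @slot seed master seed; all chain RNGs and initial values derive from it.
#' @slot initDispersion over-dispersion factor applied to prior draws used as
#'   initial values, so chains start from deliberately spread states.
#' @export
setClass("McmcConfig", representation(
  nIterations = "integer",
  nBurnin = "integer",
  thin = "integer",
  nChains = "integer",
  seed = "integer",
  initDispersion = "numeric"
))

setValidity("McmcConfig", function(object) {
  msg <- character(0)
  if (object@nBurnin < 0L || object@nIterations <= object@nBurnin)
    msg <- c(msg, "need nIterations > nBurnin >= 0")
  if (object@thin < 1L) msg <- c(msg, "thin must be >= 1")
  if (object@nChains < 2L) msg <- c(msg, "need at least 2 chains")
  if (object@initDispersion <= 0) msg <- c(msg, "initDispersion must be positive")
  if (length(msg)) msg else TRUE
})

#' PosteriorSamples: retained MCMC draws with convergence diagnostics
#'
#' @slot draws numeric array, iterations x chains x parameters, with parameter
#'   names on the third dimension (top-level parameters, detection cells
#'   \code{p_*}, and latent \code{logN[s,t]}, \code{alpha[m,t]},
#'   \code{delta[m]}).
#' @slot config the \code{\linkS4class{McmcConfig}} used.
#' @slot structure the study structure of the fitted dataset.
#' @slot design the detection design used.
#' @slot beta2 the fixed ground baseline logit of this fit.
#' @slot rhat named split-chain potential scale reduction factors.
#' @slot ess named effective sample sizes.
#' @export
setClass("PosteriorSamples", representation(
  draws = "array",
  config = "McmcConfig",
  structure = "StudyStructure",
  design = "DetectionDesign",
  beta2 = "numeric",
  rhat = "numeric",
  ess = "numeric"
))

setValidity("PosteriorSamples", function(object) {
  d <- dim(object@draws)
  if (length(d) != 3L)
    return("draws must be an iterations x chains x parameters array")
  cfg <- object@config
  if (d[1] != (cfg@nIterations - cfg@nBurnin) %/% cfg@thin)
    return("retained draw count disagrees with the chain configuration")
  if (d[2] != cfg@nChains) return("chain count disagrees with the configuration")
  if (is.null(dimnames(object@draws)[[3]]))
    return("parameters must be named")
  TRUE
})

#' AbundanceIndexSeries: posterior abundance-index summaries
#'
#' One row per (unit, year) for a chosen month, where units are sites or
#' protected areas (area series are per-draw sums over member sites, then
#' summarised).
#'
#' @slot table data.frame with columns level, unit, year, month, mean, lower,
#'   upper.
#' @slot month the month index summarised (1 = September).
#' @slot level "site" or "area".
#' @slot indexDraws draws x units x years array of per-draw index values.
#' @export
setClass("AbundanceIndexSeries", representation(
  table = "data.frame",
  month = "integer",
  level = "character",
  indexDraws = "array"
))

setValidity("AbundanceIndexSeries", function(object) {
  tb <- object@table
  need <- c("level", "unit", "year", "month", "mean", "lower", "upper")
  if (!all(need %in% names(tb))) return("missing summary columns")
  if (any(tb$lower < 0)) return("abundance indices cannot be negative")
  if (any(tb$mean < tb$lower | tb$mean > tb$upper))
    return("credible interval must contain the posterior mean")
  TRUE
})

#' DetectionSummary: posterior summaries of the detection cells
#'
#' @slot table data.frame: one row per detection cell present in the fit, with
#'   posterior mean, SD and equal-tailed 95\% credible interval of p.
#' @slot ratioMean,ratioSD matrices of pairwise posterior ratios p_a / p_b.
#' @slot exceedance matrix: fraction of cell a's draws above the upper 95\%
#'   credible limit of cell b.
#' @slot pDraws draws x cells matrix of pooled-chain detection draws.
#' @export
setClass("DetectionSummary", representation(
  table = "data.frame",
  ratioMean = "matrix",
  ratioSD = "matrix",
  exceedance = "matrix",
  pDraws = "matrix"
))

setValidity("DetectionSummary", function(object) {
  tb <- object@table
  if (any(tb$mean <= 0 | tb$mean >= 1))
    return("detection means must lie strictly in (0, 1)")
  # the anchored cell has a degenerate (zero-width) interval
  if (any(tb$lower > tb$upper))
    return("credible interval lower limit cannot exceed the upper limit")
  if (any(abs(diag(object@ratioMean) - 1) > 1e-12))
    return("the ratio of a cell with itself must be 1")
  TRUE
})
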