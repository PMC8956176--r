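#' @include AllClasses.R mcmc.R diagnostics.R
NULL

#' Assemble a pipeline run configuration
#'
#' Every field has a default; a fully defaulted configuration simulates the
#' tiny fixture and runs it end to end. Month indices are study months
#' (1 = September); study years map to calendar years through
#' \code{yearOffset} (year 1 = 1975 by default).
#'
#' @param dataPath optional CSV of counts; when \code{NULL} the fixture at
#'   \code{scale} is simulated instead.
#' @param outDir output directory (created if needed).
#' @param species species label.
#' @param scale fixture scale used when simulating.
#' @param priors optional \code{\linkS4class{PriorSpec}} override.
#' @param config an \code{\linkS4class{McmcConfig}}.
#' @param beta2 fixed ground baseline logit.
#' @param month month index summarised by the abundance series (5 = January).
#' @param yearOffset calendar year of study year 1 minus 1.
#' @param seed master seed for every source of randomness in the run.
#' @return a \code{runConfig} list.
#' @export
runConfig <- function(dataPath = NULL, outDir = tempfile("ssmrun"),
                      species = "synthetic", scale = "tiny", priors = NULL,
                      config = mcmcConfig(), beta2 = 0, month = 5L,
                      yearOffset = 1974L, seed = 1L) {
  structure(list(dataPath = dataPath, outDir = outDir, species = species,
                 scale = scale, priors = priors, config = config,
                 beta2 = beta2, month = as.integer(month),
                 yearOffset = as.integer(yearOffset), seed = as.integer(seed)),
            class = "runConfig")
}

#' Run the full pipeline: simulate (or load), fit, summarise, check
#'
#' Executes the stages in order, writes every artefact under the output
#' directory and finishes with a manifest listing each file with its MD5
#' hash, the seeds and the chain configuration, so two runs with the same
#' configuration produce hash-identical outputs. Any stage failure aborts
#' with the stage name; artefacts of completed stages are kept.
#'
#' @param cfg a \code{\link{runConfig}}.
#' @param quiet suppress sampler progress.
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(cfg, quiet = TRUE) {
  stopifnot(inherits(cfg, "runConfig"))
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  files <- character(0)
  outFile <- function(nm) file.path(cfg$outDir, nm)

  if (is.null(cfg$dataPath)) {
    sim <- stage("simulate", {
      fx <- makeFixture(cfg$scale, seed = splitSeed(cfg$seed, 1L))
      simulateSurvey(fx)
    })
    dataset <- sim$dataset
    stage("simulate", {
      writeCounts(dataset, outFile("counts.csv"))
      writeTruth(sim$truth, outFile("truth.json"))
    })
    files <- c(files, "counts.csv", "truth.json")
  } else {
    dataset <- stage("read", readCounts(cfg$dataPath, species = cfg$species))
  }

  priors <- if (is.null(cfg$priors)) defaultPriors(dataset) else cfg$priors
  mc <- cfg$config
  mc@seed <- splitSeed(cfg$seed, 2L)
  fit <- stage("fit", fitModel(dataset, priors, mc, beta2 = cfg$beta2,
                               quiet = quiet))

  stage("fit", {
    top <- parameterNames(fit, "top")
    cells <- parameterNames(fit, "cells")
    draws <- drawsOf(fit, c(top, cells))
    utils::write.csv(data.frame(draw = seq_len(nrow(draws)), draws),
                     outFile("draws_top.csv"), row.names = FALSE)
    conv <- list(
      rhat = as.list(fit@rhat[top]),
      ess = as.list(fit@ess[top]),
      maxRhatTop = max(fit@rhat[top], na.rm = TRUE),
      converged = max(fit@rhat[top], na.rm = TRUE) < 1.1,
      fixed = list(beta2 = cfg$beta2, nu = 4),
      priors = lapply(priors@entries, function(e)
        list(family = e$family, pars = e$pars)),
      dims = list(nSites = nSites(dataset), nYears = nYears(dataset),
                  nMonths = nMonths(dataset)),
      config = list(nIterations = mc@nIterations, nBurnin = mc@nBurnin,
                    thin = mc@thin, nChains = mc@nChains, seed = mc@seed))
    jsonlite::write_json(conv, outFile("convergence.json"), auto_unbox = TRUE,
                         digits = NA)
  })
  files <- c(files, "draws_top.csv", "convergence.json")

  stage("summarize", {
    ds <- detectionSummary(fit)
    utils::write.csv(ds@table, outFile("detection.csv"), row.names = FALSE)
    idx <- abundanceIndex(fit, month = cfg$month, level = "area")
    tb <- idx@table
    tb$calendarYear <- tb$year + cfg$yearOffset
    utils::write.csv(tb, outFile("abundance_index.csv"), row.names = FALSE)
  })
  files <- c(files, "detection.csv", "abundance_index.csv")

  stage("ppc", {
    ppc <- posteriorFitCheck(fit, dataset, seed = splitSeed(cfg$seed, 3L),
                             nDraws = 100L)
    jsonlite::write_json(
      list(pvalues = data.frame(method = rownames(ppc$pvalues),
                                as.data.frame(ppc$pvalues),
                                row.names = NULL),
           coverage95 = as.list(ppc$coverage95)),
      outFile("ppc.json"), auto_unbox = TRUE, digits = NA)
  })
  files <- c(files, "ppc.json")

  manifest <- list(
    seed = cfg$seed,
    species = dataset@species,
    config = list(nIterations = mc@nIterations, nBurnin = mc@nBurnin,
                  thin = mc@thin, nChains = mc@nChains, seed = mc@seed,
                  beta2 = cfg$beta2),
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(cfg$outDir, files))), files)))
  jsonlite::write_json(manifest, outFile("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
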