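# Shared fixtures and cached fits. Fits are memoised per test run so several
# test files (and several acceptance criteria) can reuse the same chains.

fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixtureCache)) {
    assign(key, force(expr), envir = fixtureCache)
  }
  get(key, envir = fixtureCache)
}

tinySim <- function(seed = 20260924L, exact = FALSE) {
  cached(paste0("tinySim_", seed, "_", exact),
         simulateSurvey(makeFixture("tiny", seed = seed), exact = exact))
}

# the workhorse fit used by convergence, sensitivity and index tests
tinyFit <- function() {
  cached("tinyFit", fitModel(
    tinySim()$dataset,
    config = mcmcConfig(nIterations = 3000L, nBurnin = 1000L, thin = 2L,
                        nChains = 3L, seed = 107L)))
}

# short chain config for replicate-heavy checks
shortConfig <- function(seed) {
  mcmcConfig(nIterations = 1600L, nBurnin = 600L, thin = 2L, nChains = 3L,
             seed = seed)
}

# 20 simulate-fit replicates at tiny scale, shared by the parameter-recovery
# and predictive-check calibration tests
recoveryFits <- function(nRep = 20L) {
  cached(paste0("recovery_", nRep), {
    lapply(seq_len(nRep), function(k) {
      sim <- simulateSurvey(makeFixture("tiny", seed = 50000L + 13L * k))
      fit <- fitModel(sim$dataset, config = shortConfig(seed = 900L + k))
      list(sim = sim, fit = fit)
    })
  })
}

# a synthetic PosteriorSamples built from explicit draws, for diagnostics
# unit tests that need no MCMC
fakeSamples <- function(draws3d, structure = studyStructureOf("tiny"),
                        config = mcmcConfig(seed = 1L)) {
  # a config consistent with the array shape (>= 2 chains required)
  cfg <- mcmcConfig(nIterations = dim(draws3d)[1] + 10L, nBurnin = 10L,
                    thin = 1L, nChains = dim(draws3d)[2], seed = 1L)
  new("PosteriorSamples", draws = draws3d, config = cfg,
      structure = structure, design = buildDetectionDesign(structure),
      beta2 = 0, rhat = numeric(0), ess = numeric(0))
}
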