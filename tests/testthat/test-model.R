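# Component log-densities of the state-space model, each checked against an
# independently coded oracle or a frozen closed-form value.

test_that("the state update is exponential growth", {
  expect_equal(stateUpdate(100, 0), 100)
  expect_equal(stateUpdate(50, log(2)), 100)
  expect_equal(stateUpdate(100, -0.10536), 90.0, tolerance = 1e-3 / 90)
  expect_error(stateUpdate(0, 0.1), "positive")
  expect_error(stateUpdate(-5, 0.1), "positive")
})

test_that("growth-rate and initial-state terms are the stated Normal densities", {
  expect_equal(growthRateLogpdf(0, 0, 1), -0.918939, tolerance = 1e-6)
  expect_equal(initialStateLogpdf(0, 0, 1), -0.918939, tolerance = 1e-6)
  # mode at the mean
  expect_true(all(growthRateLogpdf(0.3, 0.3, 0.2) >
                    growthRateLogpdf(c(0.1, 0.5), 0.3, 0.2)))
  # Normal symmetry
  expect_equal(initialStateLogpdf(2 + 0.7, 2, 0.5),
               initialStateLogpdf(2 - 0.7, 2, 0.5))
  # brute-force density oracle on a grid
  grid <- seq(-3, 3, length.out = 41)
  oracle <- -0.5 * log(2 * pi * 0.49) - (grid - 0.4)^2 / (2 * 0.49)
  expect_equal(growthRateLogpdf(grid, 0.4, 0.7), oracle, tolerance = 1e-10)
  expect_error(growthRateLogpdf(0, 0, 0), "positive")
  expect_error(initialStateLogpdf(0, 0, -1), "positive")
})

test_that("the seasonal term sums the random walk and the interannual deviations", {
  # all-zero states: one standard-normal log-density per free term
  expect_equal(seasonalLogpdf(rep(0, 7), matrix(0, 7, 1), 1, 1),
               -0.918939 * (6 + 7), tolerance = 1e-5)
  expect_error(seasonalLogpdf(c(0.2, 0, 0), matrix(0, 3, 2), 1, 1), "anchor")
  # per-term oracle on a random instance
  set.seed(42)
  delta <- c(0, cumsum(rnorm(6, 0, 0.3)))
  alpha <- matrix(rnorm(7 * 5, delta, 0.2), 7, 5)
  oracle <- 0
  for (m in 2:7) oracle <- oracle + dnorm(delta[m], delta[m - 1], 0.3, log = TRUE)
  for (m in 1:7) for (t in 1:5)
    oracle <- oracle + dnorm(alpha[m, t], delta[m], 0.2, log = TRUE)
  expect_equal(seasonalLogpdf(delta, alpha, 0.3, 0.2), oracle,
               tolerance = 1e-10)
})

test_that("the detection index is the anchored inverse logit", {
  expect_identical(detectionProbability(0, 0), 0.5)
  expect_equal(detectionProbability(0.4054651, 0), 0.6, tolerance = 1e-6)
  # strictly increasing in beta + gamma and bounded in (0, 1)
  eta <- seq(-30, 30, length.out = 201)
  p <- detectionProbability(eta, 0)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p < 1))
})

test_that("the observation term is a scaled Student-t on the log scale", {
  # frozen closed form at the location: log[Gamma(2.5)/(Gamma(2) sqrt(4 pi))]
  expect_equal(observationLogpdf(1.5, 1.5, 0, 1 - 1e-15, 1, 4),
               -0.980829, tolerance = 1e-6)
  # p = 1 contributes nothing to the location
  expect_equal(observationLogpdf(2.3, 2.0, 0.3, 1 - 1e-15, 0.5, 4),
               dt(0, 4, log = TRUE) - log(0.5))
  # doubling N at fixed p and alpha shifts the location by exactly log 2
  expect_equal(observationLogpdf(log(200), log(100) + log(2), 0.1, 0.5, 0.4, 4),
               observationLogpdf(log(100), log(100), 0.1, 0.5, 0.4, 4))
  # large-nu limit: Normal within 1e-4 across a grid
  grid <- seq(-4, 4, length.out = 81)
  expect_equal(observationLogpdf(grid, 0, 0, 0.5, 0.7, 1e6),
               dnorm(grid, log(0.5), 0.7, log = TRUE), tolerance = 1e-4)
  expect_error(observationLogpdf(1, 1, 0, 0.5, -1, 4), "sigmaObs")
  expect_error(observationLogpdf(1, 1, 0, 0.5, 1, 0), "nu")
  expect_error(observationLogpdf(1, 1, 0, 1.2, 1, 4), "p must")
})

test_that("the joint density decomposes into its terms", {
  sim <- tinySim(exact = TRUE)
  params <- sim$truth$parameters
  ds <- sim$dataset
  design <- sim$truth$design
  st <- ds@structure

  # independent brute-force accumulation, term by term, cell by cell
  oracle <- 0
  for (s in seq_len(st@nSites)) {
    oracle <- oracle + dnorm(params@logN1[s], params@mu, params@sigmaSite,
                             log = TRUE)
    oracle <- oracle + dnorm(params@r[s, 1], 0, params@sigmaYear, log = TRUE)
    for (t in 2:st@nYears)
      oracle <- oracle + dnorm(params@r[s, t], params@r[s, t - 1],
                               params@sigmaYear, log = TRUE)
  }
  for (m in 2:st@nMonths)
    oracle <- oracle + dnorm(params@delta[m], params@delta[m - 1],
                             params@sigmaMonth1, log = TRUE)
  for (m in seq_len(st@nMonths)) for (t in seq_len(st@nYears))
    oracle <- oracle + dnorm(params@alpha[m, t], params@delta[m],
                             params@sigmaMonth2, log = TRUE)
  logN <- params@logN1
  for (s in seq_len(st@nSites)) {
    ln <- cumsum(c(params@logN1[s], params@r[s, -1]))
    for (t in seq_len(st@nYears)) for (m in seq_len(st@nMonths)) for (i in 1:2) {
      yv <- ds@logCounts[i, m, s, t]
      if (is.na(yv)) next
      p <- plogis(cellLinearPredictors(params)[[designCell(design, kMethods[i], s, t)]])
      z <- (yv - (ln[t] + params@alpha[m, t] + log(p))) /
        unname(params@sigmaObs[i])
      oracle <- oracle + dt(z, 4, log = TRUE) - log(unname(params@sigmaObs[i]))
    }
  }
  expect_equal(jointLogDensity(params, ds, design), unname(oracle),
               tolerance = 1e-8)

  # additivity: blanking one observed cell removes exactly its term
  idx <- which(!is.na(ds@logCounts), arr.ind = TRUE)[5, ]
  term <- unname(observationLogpdf(
    ds@logCounts[idx[1], idx[2], idx[3], idx[4]],
    log(sim$truth$latentAbundance[idx[3], idx[4]]),
    params@alpha[idx[2], idx[4]],
    sim$truth$detection[idx[1], idx[3], idx[4]],
    params@sigmaObs[idx[1]], 4))
  ds2 <- ds
  ds2@counts[idx[1], idx[2], idx[3], idx[4]] <- NA_integer_
  ds2@logCounts[idx[1], idx[2], idx[3], idx[4]] <- NA_real_
  expect_equal(jointLogDensity(params, ds2, design),
               jointLogDensity(params, ds, design) - term, tolerance = 1e-8)

  # prior terms add the per-parameter log prior densities
  priors <- defaultPriors(ds)
  vec <- topLevelVector(params)
  priorSum <- sum(vapply(names(priors@entries), function(nm)
    priorLogpdf(priors@entries[[nm]], vec[[nm]]), numeric(1)))
  expect_equal(jointLogDensity(params, ds, design, priors),
               jointLogDensity(params, ds, design) + priorSum,
               tolerance = 1e-8)
})

test_that("the joint density is invariant to consistent site relabelling", {
  sim <- tinySim(exact = TRUE)
  params <- sim$truth$parameters
  ds <- sim$dataset
  st <- ds@structure
  perm <- c(3L, 1L, 2L, 6L, 4L, 5L)

  st2 <- st
  st2@areaOfSite <- st@areaOfSite[perm]
  st2@aerialIntroYear <- st@aerialIntroYear[perm]
  ds2 <- ds
  ds2@counts <- ds@counts[, , perm, , drop = FALSE]
  ds2@logCounts <- ds@logCounts[, , perm, , drop = FALSE]
  ds2@structure <- st2
  params2 <- params
  params2@logN1 <- params@logN1[perm]
  params2@r <- params@r[perm, , drop = FALSE]
  expect_equal(jointLogDensity(params2, ds2, buildDetectionDesign(st2)),
               jointLogDensity(params, ds, buildDetectionDesign(st)),
               tolerance = 1e-10)
})
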