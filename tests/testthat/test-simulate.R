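# The synthetic-data generator: forward simulation of the state, seasonal
# and observation processes plus the study's missingness structure.

test_that("degenerate growth reproduces the deterministic state process", {
  st <- studyStructureOf("tiny")
  base <- fixtureParameters()
  # vanishing innovation SD pins every growth rate at the year-1 anchor of 0
  p0 <- modelParameters(mu = log(100), sigmaSite = 1e-12, sigmaYear = 1e-12,
                        sigmaMonth1 = base@sigmaMonth1,
                        sigmaMonth2 = base@sigmaMonth2,
                        sigmaObs = base@sigmaObs, beta1 = base@beta1)
  truth <- generateTruth(st, p0, seed = 1L)
  expect_equal(truth$latentAbundance,
               matrix(100, nSites(st), nYears(st)), tolerance = 1e-6)
  # two doublings: r fixed at log 2 from year 1 on
  expect_equal(stateUpdate(stateUpdate(50, log(2)), log(2)), 200)
})

test_that("growth-rate innovations have the stated Normal moments", {
  st <- studyStructureOf("tiny")
  params <- fixtureParameters()
  diffs <- vapply(seq_len(1000), function(k) {
    truth <- generateTruth(st, params, seed = 3000L + k)
    truth$parameters@r[1, 2] - truth$parameters@r[1, 1]
  }, numeric(1))
  expect_equal(mean(diffs), 0, tolerance = 4 * params@sigmaYear / sqrt(1000))
  expect_equal(sd(diffs), params@sigmaYear, tolerance = 0.15 * params@sigmaYear)
})

test_that("generation is deterministic given the seed and validates inputs", {
  st <- studyStructureOf("tiny")
  params <- fixtureParameters()
  t1 <- generateTruth(st, params, seed = 5L)
  t2 <- generateTruth(st, params, seed = 5L)
  expect_identical(t1$parameters@r, t2$parameters@r)
  d1 <- generateCounts(t1, st, seed = 9L)
  d2 <- generateCounts(t2, st, seed = 9L)
  expect_identical(d1@counts, d2@counts)
  bad <- params
  bad@sigmaYear <- -1
  expect_error(generateTruth(st, bad, seed = 1L), "sigmaYear")
  expect_error(modelParameters(mu = 1, sigmaSite = 1, sigmaYear = 1,
                               sigmaMonth1 = 0, sigmaMonth2 = 1,
                               sigmaObs = c(1, 1)), "sigmaMonth1")
  # truth/structure mismatch
  expect_error(generateCounts(t1, studyStructureOf("small"), seed = 1L),
               "disagree")
})

test_that("vanishing observation noise returns the located count", {
  st <- studyStructureOf("tiny")
  st@missingnessRate[] <- 0
  st@aerialIntroYear[] <- 1L
  base <- fixtureParameters()
  p0 <- modelParameters(mu = log(400), sigmaSite = 0.5, sigmaYear = 0.1,
                        sigmaMonth1 = 0.2, sigmaMonth2 = 0.1,
                        sigmaObs = c(aerial = 1e-9, ground = 1e-9),
                        beta1 = base@beta1, gammaAerial = base@gammaAerial,
                        gammaGround = base@gammaGround)
  truth <- generateTruth(st, p0, seed = 2L)
  ds <- generateCounts(truth, st, seed = 3L)
  N <- truth$latentAbundance
  for (i in 1:2) for (m in c(1L, 4L)) {
    expected <- N * truth$detection[i, , ] *
      exp(matrix(truth$parameters@alpha[m, ], nrow(N), ncol(N), byrow = TRUE))
    # count = round(exp(y) - 1) at y exactly the location, so the count
    # equals N p exp(alpha) within the transform's rounding and offset
    expect_true(all(abs(ds@counts[i, m, , ] - (expected - 1)) <= 0.5 + 1e-6))
    expect_true(all(abs(ds@counts[i, m, , ] - expected) <= 1.5))
  }
})

test_that("missingness matches its Bernoulli rates and censors pre-introduction years", {
  st <- studyStructureOf("tiny")
  st@missingnessRate["ground", ] <- 0.5
  truth <- generateTruth(st, fixtureParameters(), seed = 11L)
  missFrac <- vapply(1:30, function(k) {
    ds <- generateCounts(truth, st, seed = 600L + k)
    mean(is.na(ds@counts[2, , , ]))
  }, numeric(1))
  nCells <- nMonths(st) * nSites(st) * nYears(st)
  se <- sqrt(0.5 * 0.5 / (30 * nCells))
  expect_lt(abs(mean(missFrac) - 0.5), 3 * se)
  # aerial cells before a site's introduction year are always missing
  lateSite <- which(st@aerialIntroYear > 1L)[1]
  ds <- generateCounts(truth, st, seed = 601L)
  expect_true(all(is.na(
    ds@counts[1, , lateSite, seq_len(st@aerialIntroYear[lateSite] - 1L)])))
})

test_that("missingness is independent of the latent abundance (MCAR)", {
  st <- studyStructureOf("tiny")
  params <- fixtureParameters()
  pairs <- do.call(rbind, lapply(1:40, function(k) {
    sim <- simulateSurvey(makeFixture("tiny", seed = 7000L + k))
    logN <- log(sim$truth$latentAbundance)
    miss <- apply(is.na(sim$dataset@counts[2, , , , drop = FALSE]), c(3, 4), mean)
    cbind(as.vector(logN), as.vector(miss))
  }))
  expect_lt(abs(cor(pairs[, 1], pairs[, 2])), 0.05)
})

test_that("heavy observation tails carry the Student-t(4) mass", {
  st <- studyStructureOf("tiny")
  st@missingnessRate[] <- 0
  st@aerialIntroYear[] <- 1L
  base <- fixtureParameters()
  p0 <- modelParameters(mu = log(300), sigmaSite = 0.5, sigmaYear = 0.1,
                        sigmaMonth1 = 0.2, sigmaMonth2 = 0.1,
                        sigmaObs = c(aerial = 0.5, ground = 0.5), nu = 4,
                        beta1 = base@beta1)
  truth <- generateTruth(st, p0, seed = 21L)
  devs <- unlist(lapply(1:20, function(k) {
    ds <- generateCounts(truth, st, seed = 800L + k, exact = TRUE)
    loc <- log(truth$latentAbundance)
    dv <- array(NA_real_, dim(ds@logCounts))
    for (i in 1:2) for (m in seq_len(nMonths(st)))
      dv[i, m, , ] <- ds@logCounts[i, m, , ] - (loc + log(truth$detection[i, , ]) +
        matrix(truth$parameters@alpha[m, ], nrow(loc), ncol(loc), byrow = TRUE))
    dv
  }))
  # tail mass beyond 2 scale units, against the pt() oracle
  target <- 2 * pt(-2, df = 4)
  emp <- mean(abs(devs) > 2 * 0.5)
  se <- sqrt(target * (1 - target) / length(devs))
  expect_lt(abs(emp - target), 4 * se)
})

test_that("with p = 0.5 everywhere and no seasonality the expected log observation is log N + log 0.5", {
  st <- studyStructureOf("tiny")
  st@missingnessRate[] <- 0
  st@aerialIntroYear[] <- 1L
  p0 <- modelParameters(mu = log(500), sigmaSite = 0.4, sigmaYear = 0.08,
                        sigmaMonth1 = 1e-12, sigmaMonth2 = 1e-12,
                        sigmaObs = c(aerial = 0.3, ground = 0.3),
                        beta1 = 0, beta2 = 0)
  truth <- generateTruth(st, p0, seed = 31L)
  expect_true(all(abs(truth$detection - 0.5) < 1e-12))
  yMeans <- rowMeans(vapply(1:50, function(k) {
    ds <- generateCounts(truth, st, seed = 900L + k, exact = TRUE)
    as.vector(ds@logCounts[, 1, , ])
  }, numeric(2 * nSites(st) * nYears(st))))
  expected <- rep(as.vector(log(truth$latentAbundance) + log(0.5)), each = 2)
  expect_equal(mean(yMeans - expected), 0, tolerance = 0.03)
})

test_that("the generator's accumulated log-density matches the model's joint density", {
  sim <- tinySim(exact = TRUE)
  accumulated <- sim$truth$logDensity + attr(sim$dataset, "logDensity")
  expect_equal(jointLogDensity(sim$truth$parameters, sim$dataset,
                               sim$truth$design),
               accumulated, tolerance = 1e-8)
})
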