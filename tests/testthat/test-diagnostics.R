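# Posterior summary machinery: exceedance, ratios, abundance index, rank
# correlation, predictive checks. Most tests fabricate draws directly.

test_that("exceedance probability counts draws above the upper credible limit", {
  expect_equal(exceedanceProbability(c(10, 11, 12), c(1, 2, 3)), 1.0)
  set.seed(8)
  x <- rnorm(20000)
  expect_equal(exceedanceProbability(x, x), 0.025, tolerance = 0.005)
  # enumeration oracle on a 10-draw toy set
  a <- c(0.1, 0.25, 0.3, 0.42, 0.5, 0.55, 0.61, 0.7, 0.85, 0.9)
  b <- c(0.2, 0.3, 0.32, 0.4, 0.45, 0.5, 0.52, 0.6, 0.62, 0.65)
  upper <- quantile(b, 0.975, names = FALSE)
  expect_equal(exceedanceProbability(a, b), sum(a > upper) / length(a))
  expect_error(exceedanceProbability(numeric(0), 1:3), "empty")
})

test_that("detection ratios are per-draw and paired", {
  same <- rep(0.4, 50)
  r <- detectionRatio(same, same)
  expect_equal(r$mean, 1.0)
  expect_equal(r$sd, 0)
  expect_equal(detectionRatio(rep(0.6, 10), rep(0.3, 10))$mean, 2.0)
  set.seed(5)
  a <- runif(10, 0.3, 0.9); b <- runif(10, 0.1, 0.8)
  expect_equal(detectionRatio(a, b)$ratios, a / b)
  expect_equal(detectionRatio(a, b)$mean, mean(a / b))
  expect_error(detectionRatio(a, b[1:5]), "paired")
})

test_that("summary operations are pure functions of the draws", {
  fit <- tinyFit()
  s1 <- detectionSummary(fit)
  s2 <- detectionSummary(fit)
  expect_identical(s1@table, s2@table)
  expect_identical(s1@exceedance, s2@exceedance)
  i1 <- abundanceIndex(fit, month = 1)
  i2 <- abundanceIndex(fit, month = 1)
  expect_identical(i1@table, i2@table)
  # structural invariants of the summary
  expect_true(all(diag(s1@ratioMean) == 1))
  # strict interval width everywhere except the degenerate anchored cell
  free <- s1@table$cell != "p_vigueirat"
  expect_true(all(s1@table$lower[free] < s1@table$upper[free]))
  expect_true(all(s1@table$lower <= s1@table$upper))
})

test_that("the abundance index reduces to N at the September anchor and sums by area", {
  # fabricated posterior: two chains of known logN and alpha draws
  st <- studyStructureOf("tiny")
  S <- nSites(st); T <- nYears(st); M <- nMonths(st)
  nIt <- 50L; nCh <- 2L
  logN <- matrix(log(100 + 10 * (1:S)), S, T)   # constant over years
  pars <- c(as.vector(outer(1:S, 1:T, function(s, t) sprintf("logN[%d,%d]", s, t))),
            as.vector(outer(1:M, 1:T, function(m, t) sprintf("alpha[%d,%d]", m, t))))
  draws <- array(0, c(nIt, nCh, length(pars)), dimnames = list(NULL, NULL, pars))
  for (s in 1:S) for (t in 1:T)
    draws[, , sprintf("logN[%d,%d]", s, t)] <- logN[s, t]
  fake <- fakeSamples(draws, structure = st)

  idx <- abundanceIndex(fake, month = 1)
  # alpha = 0 at every draw: the index equals N exactly, with a degenerate CI
  tb <- idx@table
  for (s in 1:S) {
    rows <- tb[tb$unit == as.character(s), ]
    expect_equal(rows$mean, rep(exp(logN[s, 1]), T))
    expect_equal(rows$lower, rows$mean)
    expect_equal(rows$upper, rows$mean)
  }
  # area series: per-draw sums over member sites, so each area's index
  # matches the summed member sites and dominates any single member
  area <- abundanceIndex(fake, month = 1, level = "area")
  for (a in unique(areaOfSite(st))) {
    sites <- which(areaOfSite(st) == a)
    got <- area@table[area@table$unit == a & area@table$year == 1, "mean"]
    expect_equal(got, sum(exp(logN[sites, 1])))
    expect_gte(got, max(exp(logN[sites, 1])))
  }
  expect_error(abundanceIndex(fake, month = 9), "out of range")
})

test_that("rank correlation against counts matches a rank-then-Pearson oracle", {
  st <- studyStructureOf("tiny")
  S <- nSites(st); T <- nYears(st); M <- nMonths(st)
  set.seed(31)
  pars <- c(as.vector(outer(1:S, 1:T, function(s, t) sprintf("logN[%d,%d]", s, t))),
            as.vector(outer(1:M, 1:T, function(m, t) sprintf("alpha[%d,%d]", m, t))))
  draws <- array(0, c(20, 2, length(pars)), dimnames = list(NULL, NULL, pars))
  # distinct integer abundances so ranks are tie-free
  lnTrue <- matrix(log(sample(seq(50L, 20000L, by = 7L), S * T)), S, T)
  for (s in 1:S) for (t in 1:T)
    draws[, , sprintf("logN[%d,%d]", s, t)] <- lnTrue[s, t]
  fake <- fakeSamples(draws, structure = st)
  idx <- abundanceIndex(fake, month = 3)

  # counts equal to the index: perfect rank agreement
  counts <- array(NA_integer_, c(2, M, S, T))
  counts[1, 3, , ] <- round(exp(lnTrue))
  ds <- surveyDataset(counts, st)
  expect_equal(correlateWithCounts(idx, ds, "aerial"), 1)
  # reversed ranks: perfect disagreement
  ranks <- rank(exp(lnTrue))
  rev <- array(NA_integer_, c(2, M, S, T))
  rev[1, 3, , ] <- as.integer(max(ranks) - ranks + 1)
  expect_equal(correlateWithCounts(idx, surveyDataset(rev, st), "aerial"), -1)
  # 6-point oracle: rank then Pearson, against a sparse observation set
  few <- array(NA_integer_, c(2, M, S, T))
  cells <- cbind(s = 1:6, t = c(2, 4, 5, 7, 8, 10))
  obs <- c(120L, 45L, 300L, 80L, 80L, 15L)
  few[cbind(2, 3, cells[, "s"], cells[, "t"])] <- obs
  dsFew <- surveyDataset(few, st)
  idxMeans <- idx@table$mean[match(paste(cells[, "s"], cells[, "t"]),
                                   paste(idx@table$unit, idx@table$year))]
  oracle <- cor(rank(idxMeans), rank(obs))
  expect_equal(correlateWithCounts(idx, dsFew, "ground"), oracle)
  expect_error(correlateWithCounts(idx, surveyDataset(
    array(NA_integer_, c(2, M, S, T)), st), "aerial"), "overlap|fewer")
})

test_that("the posterior predictive check reduces to the generator at a point mass", {
  sim <- tinySim(exact = FALSE)
  st <- sim$dataset@structure
  truth <- sim$truth
  params <- truth$parameters
  S <- nSites(st); T <- nYears(st); M <- nMonths(st)
  # point-mass posterior at the generating values
  pars <- c("sigma_obs_aerial", "sigma_obs_ground",
            paste0("p_", sub("^(aerial|ground)_", "", kDetectionCells)),
            as.vector(outer(1:S, 1:T, function(s, t) sprintf("logN[%d,%d]", s, t))),
            as.vector(outer(1:M, 1:T, function(m, t) sprintf("alpha[%d,%d]", m, t))))
  draws <- array(0, c(10, 2, length(pars)), dimnames = list(NULL, NULL, pars))
  draws[, , "sigma_obs_aerial"] <- params@sigmaObs["aerial"]
  draws[, , "sigma_obs_ground"] <- params@sigmaObs["ground"]
  pCells <- cellDetection(params)
  for (k in seq_along(kDetectionCells))
    draws[, , paste0("p_", sub("^(aerial|ground)_", "", kDetectionCells[k]))] <-
      pCells[[kDetectionCells[k]]]
  ln <- log(truth$latentAbundance)
  for (s in 1:S) for (t in 1:T)
    draws[, , sprintf("logN[%d,%d]", s, t)] <- ln[s, t]
  for (m in 1:M) for (t in 1:T)
    draws[, , sprintf("alpha[%d,%d]", m, t)] <- params@alpha[m, t]
  fake <- fakeSamples(draws, structure = st)

  # replicate 1 of the check shares the generator's observation stream: with
  # the matching seed the replicated draws equal the generator's
  genSeed <- 4242L
  dsRegen <- generateCounts(truth, st, seed = genSeed, exact = TRUE)
  ppc <- posteriorFitCheck(fake, dsRegen, seed = genSeed, nDraws = 1L)
  yRepFirst <- ppc$replicated[1, , ]
  obsMask <- !is.na(dsRegen@logCounts)
  for (i in 1:2) {
    yObs <- dsRegen@logCounts[i, , , ][obsMask[i, , , ]]
    expect_equal(unname(yRepFirst[i, ]),
                 unname(c(mean(yObs), sd(yObs), max(yObs))), tolerance = 1e-12)
  }
})

test_that("an injected outlier block is flagged by the maximum discrepancy", {
  fit <- tinyFit()
  sim <- tinySim()
  ds <- sim$dataset
  # multiply one site's ground counts by 10 across all months of one year
  cnt <- ds@counts
  # inflate the block (site, year) holding the largest observed ground count
  topCell <- which(cnt[2, , , ] == max(cnt[2, , , ], na.rm = TRUE),
                   arr.ind = TRUE)[1, ]
  tgt <- which(!is.na(cnt[2, , topCell[2], topCell[3]]))
  cnt[2, tgt, topCell[2], topCell[3]] <-
    cnt[2, tgt, topCell[2], topCell[3]] * 10
  dsOut <- surveyDataset(cnt, ds@structure)
  ppcClean <- posteriorFitCheck(fit, ds, seed = 606L, nDraws = 150L)
  ppcOut <- posteriorFitCheck(fit, dsOut, seed = 606L, nDraws = 150L)
  # clean data from the model itself sit inside the calibration band
  expect_true(all(ppcClean$pvalues > 0.01 & ppcClean$pvalues < 0.99))
  # the outlier block drives the ground maximum statistic to an extreme
  expect_lt(ppcOut$pvalues["ground", "max"], 0.05)
})
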