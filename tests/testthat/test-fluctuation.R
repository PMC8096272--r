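# Variance profiling, window convergence and the double-peak classifier.

test_that("extension variance matches analytic references", {
  expect_identical(extensionVariance(makeTrace(rep(5, 1500)), 4), 0)
  # pure Gaussian noise: sampling-error oracle SE = sigma^2 sqrt(2/(n-1))
  set.seed(1)
  n <- 10000
  tr <- makeTrace(rnorm(n, 0, 10), rate = 2000)
  se <- 100 * sqrt(2 / (n - 1))
  expect_lt(abs(extensionVariance(tr, 5) - 100), 3 * se)
  # two-level telegraph with equal dwell: closed form dL^2/4 (x n/(n-1))
  tel <- makeTrace(rep(c(-50, 50), 750))
  expect_equal(extensionVariance(tel, 5), 2500 * 1500 / 1499,
               tolerance = 1e-12)
  expect_error(extensionVariance(tel, 10), "window longer")
})

test_that("variance converges with window length and is flat for white noise", {
  # white noise: expectation flat across windows (averaged over replicates)
  set.seed(2)
  wins <- seq(0.5, 5, by = 0.5)
  flat <- rowMeans(replicate(60, {
    varianceConvergence(makeTrace(rnorm(1500, 0, 10)), wins)$variance_nm2
  }))
  expect_lt(diff(range(flat)) / mean(flat), 0.1)
  # hopping trace at the transition midpoint: non-decreasing in expectation
  # and >= 95% of the asymptote by ~3 s with default kinetics
  set.seed(3)
  curves <- replicate(120, {
    tr <- simulateTrace(0.69, -40, mutCfg, defPrm, FALSE)
    varianceConvergence(tr, wins)$variance_nm2
  })
  avg <- rowMeans(curves)
  expect_true(all(diff(avg) > -0.02 * max(avg)))
  expect_gt(avg[wins == 3] / avg[wins == 5], 0.95)
})

test_that("variance profiles preserve grid order and degenerate inputs", {
  grid <- seq(0.3, 0.7, by = 0.05)
  tVec <- (0:299) / 300
  trs <- lapply(grid, function(f)
    new("Trace", force = f, turns = -40, time = tVec,
        extension = rep(100, 300), meta = list()))
  ramp <- new("ForceRamp", traces = trs, forceGrid = grid, turns = -40,
              g4Available = FALSE, config = wtCfg, params = defPrm)
  prof <- varianceProfile(ramp, window = 1)
  expect_identical(prof@force, grid)
  expect_identical(prof@variance, rep(0, length(grid)))
  expect_length(prof@variance, length(grid))
})

test_that("peak detection classifies constructed profiles correctly", {
  grid <- defaultForceGrid()
  bump <- function(mu, h, s = 0.05) h * exp(-(grid - mu)^2 / (2 * s^2))
  single <- makeProfile(grid, 10 + bump(0.69, 1000))
  cS <- detectCharacteristicForces(single)
  expect_identical(peakLabel(cS), "single")
  expect_lt(abs(cS@fC - 0.69), 0.011)
  dbl <- makeProfile(grid, 10 + bump(0.37, 600) + bump(0.69, 1000))
  cD <- detectCharacteristicForces(dbl)
  expect_identical(peakLabel(cD), "double")
  expect_lt(abs(cD@fC1 - 0.37), 0.011)
  expect_lt(abs(cD@fC2 - 0.69), 0.011)
  expect_equal(cD@deltaF, cD@fC2 - cD@fC1)
  expect_identical(peakLabel(detectCharacteristicForces(
    makeProfile(grid, rep(7, length(grid))))), "no_peak")
  expect_error(detectCharacteristicForces(makeProfile(grid[1:5], rep(1, 5))),
               "at least 10")
  # sub-threshold shoulder is not called double
  weak <- makeProfile(grid, 10 + bump(0.37, 50) + bump(0.69, 1000))
  expect_identical(peakLabel(detectCharacteristicForces(weak)), "single")
})

test_that("ensemble summaries count labels and use the binomial SE", {
  grid <- defaultForceGrid()
  bump <- function(mu, h, s = 0.05) h * exp(-(grid - mu)^2 / (2 * s^2))
  singles <- replicate(8, makeProfile(grid, 10 + bump(0.69, 1000)),
                       simplify = FALSE)
  summ <- classifyEnsemble(singles)
  expect_identical(summ@nDouble, 0L)
  expect_identical(summ@pctDouble, 0)
  expect_identical(summ@sePct, 0)
  # SE formula against a Monte Carlo binomial oracle
  p <- 0.3
  n <- 50
  seFormula <- 100 * sqrt(p * (1 - p) / n)
  set.seed(4)
  seMC <- sd(100 * rbinom(1e5, n, p) / n)
  expect_equal(seFormula, seMC, tolerance = 0.02)
})

test_that("classifier recovers generator ground truth on labelled ensembles", {
  flags <- rep(c(TRUE, FALSE), 30)
  ens <- simulateEnsembleProfiles(60, -40, wtCfg, defPrm, seed = 11,
                                  forceGrid = shortGrid, g4Available = flags)
  det <- lapply(ens$profiles, detectCharacteristicForces)
  lab <- vapply(det, peakLabel, character(1))
  sens <- mean(lab[flags] == "double")
  spec <- mean(lab[!flags] != "double")
  expect_gte(sens, 0.9)
  expect_gte(spec, 0.9)
  # characteristic-force estimates are unbiased (< 1.5 grid steps)
  f1 <- vapply(det, function(d) d@fC1, numeric(1))
  f2 <- vapply(det, function(d) d@fC2, numeric(1))
  expect_lt(abs(mean(f1, na.rm = TRUE) - 0.37), 0.015)
  expect_lt(abs(mean(f2, na.rm = TRUE) - 0.69), 0.015)
})

test_that("double-peak rate is stable under halving the smoothing width", {
  ens <- simulateEnsembleProfiles(80, -40, wtCfg, defPrm, seed = 12,
                                  forceGrid = shortGrid)
  pct <- function(sd) classifyEnsemble(ens$profiles, smoothSd = sd)@pctDouble
  expect_lt(abs(pct(0.03) - pct(0.015)), 5)
})

test_that("mean curves summarise ramps and cohorts consistently", {
  grid <- seq(0.3, 0.6, by = 0.05)
  ramp <- simulateRamp(-40, wtCfg, defPrm, TRUE, forceGrid = grid, seed = 13)
  mc <- rampMeanCurve(ramp)
  expect_identical(mc$force_pN, grid)
  expect_identical(mc$ext_mean_nm,
                   vapply(ramp@traces, function(t) mean(t@extension),
                          numeric(1)))
  ens <- simulateEnsembleProfiles(4, -40, wtCfg, defPrm, forceGrid = grid,
                                  seed = 14, g4Available = TRUE)
  emc <- ensembleMeanCurve(ens$profiles)
  expect_identical(emc$n, rep(4L, length(grid)))
  expect_identical(emc$ext_mean_nm,
                   rowMeans(vapply(ens$profiles, function(p) p@meanExtension,
                                   numeric(length(grid)))))
})
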