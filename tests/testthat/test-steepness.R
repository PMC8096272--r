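# Logistic steepness fits, S0 mixture analysis and the rank-sum comparison.

test_that("logistic fitting recovers parameters exactly on clean curves", {
  clean <- syntheticLogisticCurve(a = 0, b = 2000, F1 = 0.6, S0 = 0.52,
                                  baseSd = 0, transSd = 0)
  fit <- fitLogistic(clean)
  expect_true(fit$converged)
  expect_lt(abs(fit$a - 0), 1e-3)
  expect_lt(abs(fit$b - 2000) / 2000, 1e-3)
  expect_lt(abs(fit$F1 - 0.6) / 0.6, 1e-3)
  expect_lt(abs(fit$S0 - 0.52) / 0.52, 1e-3)
  # increasing curves fit with b < 0 under the same printed form
  inc <- syntheticLogisticCurve(baseSd = 0, transSd = 0)
  fitInc <- fitLogistic(inc)
  expect_lt(fitInc$b, 0)
  expect_lt(abs(fitInc$S0 - 0.52) / 0.52, 1e-3)
  expect_error(fitLogistic(inc[1:5, ]), "at least 8")
})

test_that("steepness is recovered at ensemble-like noise for wt and mut", {
  set.seed(21)
  s0w <- s0m <- numeric(40)
  for (i in seq_len(40)) {
    seed <- 5000 + i   # paired noise seeds for the two constructs
    s0w[i] <- fitLogistic(syntheticLogisticCurve(S0 = 0.52, seed = seed))$S0
    s0m[i] <- fitLogistic(syntheticLogisticCurve(S0 = 0.64, seed = seed))$S0
  }
  expect_lt(abs(median(s0w) - 0.52), 0.1)
  expect_lt(abs(median(s0m) - 0.64), 0.1)
  expect_gt(mean(s0m > s0w), 0.75)
})

test_that("G4-available ramps yield shallower (larger S0) mean curves", {
  flags <- rep(c(TRUE, FALSE), 15)
  ens <- simulateEnsembleProfiles(30, -40, wtCfg, defPrm, seed = 22,
                                  forceGrid = shortGrid, g4Available = flags)
  s0 <- vapply(ens$profiles, function(p) {
    fitLogistic(data.frame(force_pN = p@force,
                           ext_mean_nm = p@meanExtension))$S0
  }, numeric(1))
  expect_gt(sum(is.finite(s0)), 27)   # fits converge on nearly every ramp
  expect_gt(mean(s0[flags], na.rm = TRUE), mean(s0[!flags], na.rm = TRUE))
})

test_that("Gaussian mixture fits recover components and are order invariant", {
  set.seed(23)
  one <- rnorm(500, 0.6, 0.1)
  f1 <- fitS0Mixture(one, 1)
  expect_equal(f1$means, 0.6, tolerance = 3 * 0.1 / sqrt(500))
  expect_equal(f1$sds, 0.1, tolerance = 0.02)
  x <- c(rnorm(3150, 0.55, 0.12), rnorm(1850, 1.05, 0.15))
  f2 <- fitS0Mixture(x, 2)
  expect_equal(f2$weights[2], 0.37, tolerance = 0.03)
  expect_lt(f2$means[1], f2$means[2])
  expect_equal(sum(f2$weights), 1, tolerance = 1e-9)
  perm <- fitS0Mixture(sample(x), 2)
  expect_equal(perm$weights, f2$weights, tolerance = 0.01)
  expect_equal(perm$means, f2$means, tolerance = 0.01)
  # BIC prefers the matching model on unimodal vs bimodal data
  expect_identical(selectS0Mixture(x)$k, 2L)
  expect_identical(selectS0Mixture(one)$k, 1L)
  expect_error(fitS0Mixture(one[1:10], 2), "at least 30")
})

test_that("rank-sum comparison matches exhaustive enumeration and separates groups", {
  a <- c(1.2, 3.4, 2.2, 5.0)
  b <- c(2.0, 4.1, 0.5, 1.1)
  w <- suppressWarnings(compareS0Distributions(a, b))
  # brute-force Mann-Whitney U over all pairs
  expect_equal(unname(w$statistic), sum(outer(a, b, ">")))
  # exact enumeration of the null: p-value of the normal approximation is
  # within 0.1 of the exhaustive tail probability at n = 4 + 4
  pool <- c(a, b)
  combs <- combn(8, 4)
  uNull <- apply(combs, 2, function(idx)
    sum(outer(pool[idx], pool[-idx], ">")))
  pExact <- mean(abs(uNull - 8) >= abs(unname(w$statistic) - 8))
  expect_lt(abs(w$p.value - pExact), 0.1)
  set.seed(24)
  same <- rnorm(50)
  expect_gt(compareS0Distributions(same, same)$p.value, 0.9)
  expect_lt(compareS0Distributions(rnorm(100, 0.5, 0.1),
                                   rnorm(100, 1.0, 0.1))$p.value, 0.001)
  expect_warning(compareS0Distributions(a, b), "fewer than 10")
})
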