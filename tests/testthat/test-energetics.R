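# Energy per relaxed turn, transition-energy ratio, ledger, work area and
# supercoiling density.

test_that("alpha per turn follows pi sqrt(8 B F) and its scaling law", {
  expect_identical(alphaPerTurn(0), 0)
  # direct evaluation: pi * sqrt(8 * 46 * 4.11 * 0.69)
  expect_equal(alphaPerTurn(0.69, 46, 298), pi * sqrt(8 * 46 * 4.11 * 0.69),
               tolerance = 1e-12)
  expect_equal(alphaPerTurn(0.69), 101.5, tolerance = 0.001)
  expect_equal(pNnmToKcalMol(alphaPerTurn(0.69)), 14.6, tolerance = 0.001)
  expect_equal(alphaPerTurn(4 * 0.37) / alphaPerTurn(0.37), 2,
               tolerance = 1e-12)
  expect_error(alphaPerTurn(-1), "force")
})

test_that("energy ratio is sqrt(F1/F2) and identical to the alpha ratio", {
  expect_equal(round(energyRatio(0.37, 0.69), 2), 0.73)
  expect_identical(energyRatio(0.5, 0.5), 1)
  expect_identical(energyRatio(1, 4), 0.5)
  expect_error(energyRatio(0, 1), "forces")
  set.seed(31)
  f1 <- runif(1000, 0.01, 5)
  f2 <- runif(1000, 0.01, 5)
  expect_equal(energyRatio(f1, f2), alphaPerTurn(f1) / alphaPerTurn(f2),
               tolerance = 1e-12)
})

test_that("ledger arithmetic reproduces the duplex versus G4-path bookkeeping", {
  led <- g4Ledger(120, energyRatio(0.37, 0.69))
  expect_equal(round(led$eG4Path), 88)
  expect_equal(round(led$netGain), 32)
  expect_identical(g4Ledger(100, 1)$netGain, 0)
  expect_identical(g4Ledger(100, 0.5), list(eG4Path = 50, netGain = 50))
  # full-precision consistency: cost + gain = input
  expect_identical(led$eG4Path + led$netGain, 120)
  obj <- energyLedger()
  expect_equal(obj@ratio, sqrt(0.37 / 0.69), tolerance = 1e-12)
  expect_equal(obj@netGain, (1 - sqrt(0.37 / 0.69)) * 120, tolerance = 1e-12)
  # net gain is close to 3 x 10 kcal/mol per-G4 expectation
  expect_lt(abs(obj@netGain - obj@nG4 * obj@perG4Gain), 5)
})

test_that("work area integrates the curve gap with exact unit conversion", {
  f <- seq(0, 2, by = 0.01)
  same <- data.frame(force_pN = f, ext_mean_nm = wlcExtension(f))
  expect_equal(as.numeric(workArea(same, same)), 0, tolerance = 1e-12)
  # rectangle: 100 nm gap over exactly 1 pN -> 100 pN nm
  hi <- data.frame(force_pN = f, ext_mean_nm = 100)
  lo <- data.frame(force_pN = f, ext_mean_nm = 0)
  a <- suppressWarnings(workArea(hi, lo, fRange = c(0.5, 1.5)))
  expect_equal(attr(a, "pNnm"), 100, tolerance = 1e-9)
  expect_equal(as.numeric(a), pNnmToKcalMol(100), tolerance = 1e-9)
  expect_warning(workArea(hi, lo, fRange = c(0.5, 1.5)), "coincide")
  far <- data.frame(force_pN = f + 10, ext_mean_nm = 0)
  expect_error(workArea(hi, far), "overlap")
})

test_that("supercoiling density implements nt / (Nb / helical repeat)", {
  expect_identical(supercoilDensity(0, 6680), 0)
  expect_equal(supercoilDensity(-40, 6680), -0.0623, tolerance = 1e-3)
  # the base-pair count back-computed from a printed density of -0.070
  expect_equal(supercoilDensity(-40, 5943), -0.070, tolerance = 1e-4)
  expect_error(supercoilDensity(-40, 0), "Nb")
})

test_that("pN nm to kcal/mol conversion uses Avogadro over 4184", {
  expect_identical(pNnmToKcalMol(0), 0)
  expect_equal(pNnmToKcalMol(1), 0.1439326, tolerance = 1e-6)
  expect_equal(pNnmToKcalMol(101.5), 14.609, tolerance = 1e-3)
})
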