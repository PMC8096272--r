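# Three-state generator: occupancies, mean extension, trace simulation,
# ramps and ensembles.

test_that("state occupancies are a proper distribution with logistic midpoints", {
  grid <- seq(0, 3, by = 0.05)
  for (flag in c(TRUE, FALSE)) {
    occ <- stateOccupancies(grid, -40, wtCfg, defPrm, flag)
    expect_true(all(occ >= 0))
    expect_equal(rowSums(occ), rep(1, nrow(occ)))
  }
  # first logistic midpoint: P and G occupancies cross at fC1
  occ1 <- stateOccupancies(0.37, -40, wtCfg, defPrm, TRUE)
  expect_equal(unname(occ1[1, "P"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(occ1[1, "P"]), unname(occ1[1, "G"]), tolerance = 1e-3)
  # without the G4 pathway the single transition is centred at fC2
  occ2 <- stateOccupancies(0.69, -40, wtCfg, defPrm, FALSE)
  expect_equal(unname(occ2[1, c("P", "D")]), c(0.5, 0.5), tolerance = 1e-12)
  expect_identical(unname(occ2[1, "G"]), 0)
  # deep in the denatured branch (oracle: direct logistic tail evaluation)
  occ3 <- stateOccupancies(3, -40, wtCfg, defPrm, FALSE)
  tail <- plogis((3 - defPrm@fC2) / defPrm@transitionWidth)
  expect_gt(occ3[1, "D"], 0.999)
  expect_equal(unname(occ3[1, "D"]), tail, tolerance = 1e-12)
})

test_that("occupancy preconditions are enforced", {
  expect_error(stateOccupancies(-0.1, -40), "force")
  badPrm <- defPrm
  badPrm@transitionWidth <- -1   # bypasses constructor validity on purpose
  expect_error(stateOccupancies(0.5, -40, wtCfg, badPrm), "width")
  expect_error(SimParams(transitionWidth = -1), "transitionWidth")
  expect_error(SimParams(fC1 = 0.9, fC2 = 0.5), "fC1")
})

test_that("positive or zero supercoiling suppresses both transitions", {
  grid <- seq(0.05, 3, by = 0.05)
  for (nT in c(0, 10, 40)) {
    occ <- stateOccupancies(grid, nT, wtCfg, defPrm, TRUE)
    expect_equal(unname(occ[, "G"]), rep(0, length(grid)))
    expect_equal(unname(occ[, "D"]), rep(0, length(grid)))
    expect_equal(mixingVariance(grid, nT, wtCfg, defPrm, TRUE),
                 rep(0, length(grid)))
  }
})

test_that("mean extension is collapsed at low force, WLC-like at high force, monotone", {
  expect_lt(meanExtension(0.001, -40, wtCfg, defPrm, TRUE), 0.1)
  # far above fC2 all occupancy is in the denatured state -> WLC extension
  expect_equal(meanExtension(3, -40, wtCfg, defPrm, TRUE),
               wlcExtension(3, 2000, 46), tolerance = 1e-6)
  grid <- seq(0.05, 3, by = 0.01)
  for (flag in c(TRUE, FALSE))
    expect_true(all(diff(meanExtension(grid, -40, wtCfg, defPrm, flag)) >
                      -1e-9))
  # G4 availability extends the tether earlier (oracle: occupancy formula)
  mid <- seq(0.2, 0.9, by = 0.01)
  expect_true(all(meanExtension(mid, -40, wtCfg, defPrm, TRUE) >=
                    meanExtension(mid, -40, mutCfg, defPrm, FALSE)))
})

test_that("simulated traces are reproducible, stationary and carry the programmed variance", {
  t1 <- simulateTrace(0.5, -40, wtCfg, defPrm, TRUE, seed = 42)
  t2 <- simulateTrace(0.5, -40, wtCfg, defPrm, TRUE, seed = 42)
  expect_identical(t1@extension, t2@extension)
  t3 <- simulateTrace(0.5, -40, wtCfg, defPrm, TRUE, seed = 43)
  expect_false(identical(t1@extension, t3@extension))

  # single state far from the transitions: variance = noise floor
  floor <- defPrm@beadNoiseSd^2 + defPrm@trackingNoiseSd^2
  tHigh <- simulateTrace(3, 0, wtCfg, defPrm, FALSE, seed = 7)
  expect_equal(extensionVariance(tHigh, 5), floor, tolerance = 0.25)

  # at the transition midpoint the long-window variance matches the
  # closed-form mixing variance (independent oracle: analytic formula)
  prmLong <- SimParams(dwell = 200)
  tMid <- simulateTrace(0.69, -40, mutCfg, prmLong, FALSE, seed = 8)
  vTheory <- mixingVariance(0.69, -40, mutCfg, defPrm, FALSE)[1] + floor
  expect_equal(extensionVariance(tMid, 200), vTheory, tolerance = 0.05)
  # stationary mean at the programmed occupancy-weighted extension
  expect_equal(mean(tMid@extension),
               meanExtension(0.69, -40, mutCfg, defPrm, FALSE),
               tolerance = 0.15)
})

test_that("ramps have one trace per grid force and a constant G4 flag", {
  r1 <- simulateRamp(-40, wtCfg, defPrm, TRUE, forceGrid = 0.5, seed = 1)
  expect_length(r1@traces, 1L)
  expect_length(defaultForceGrid(), 296L)
  grid <- seq(0.3, 0.8, by = 0.05)
  r <- simulateRamp(-40, wtCfg, defPrm, TRUE, forceGrid = grid, seed = 2)
  expect_length(r@traces, length(grid))
  expect_true(all(vapply(r@traces, function(t) t@turns, numeric(1)) == -40))
  expect_true(r@g4Available)
  expect_error(simulateRamp(-40, wtCfg, defPrm, TRUE, forceGrid = numeric(0)),
               "non-empty")
  # determinism of a whole ramp under the master seed
  r2 <- simulateRamp(-40, wtCfg, defPrm, TRUE, forceGrid = grid, seed = 2)
  expect_identical(lapply(r@traces, traceExtension),
                   lapply(r2@traces, traceExtension))
})

test_that("ensemble G4 flags follow the Bernoulli availability model", {
  tiny <- 0.5  # one-force grid keeps the flag test cheap
  e0 <- simulateEnsemble(20, -40, TetherConfig(pFold = 0), defPrm,
                         forceGrid = tiny, seed = 3)
  expect_false(any(attr(e0, "g4Available")))
  e1 <- simulateEnsemble(50, -40, TetherConfig(pFold = 1), defPrm,
                         forceGrid = tiny, seed = 4)
  expect_true(all(attr(e1, "g4Available")))
  eP <- simulateEnsemble(2000, -40, wtCfg, SimParams(dwell = 0.01),
                         forceGrid = tiny, seed = 5)
  frac <- mean(attr(eP, "g4Available"))
  expect_lt(abs(frac - 0.35), 3 * sqrt(0.35 * 0.65 / 2000))
})

test_that("noiseless variance profiles peak at the programmed characteristic forces", {
  grid <- defaultForceGrid()
  pWt <- makeProfile(grid, mixingVariance(grid, -40, wtCfg, defPrm, TRUE))
  cWt <- detectCharacteristicForces(pWt)
  expect_identical(peakLabel(cWt), "double")
  expect_lt(abs(cWt@fC1 - defPrm@fC1), 0.011)
  expect_lt(abs(cWt@fC2 - defPrm@fC2), 0.011)
  expect_identical(nrow(cWt@peaks), 2L)
  pMut <- makeProfile(grid, mixingVariance(grid, -40, mutCfg, defPrm, FALSE))
  cMut <- detectCharacteristicForces(pMut)
  expect_identical(peakLabel(cMut), "single")
  expect_lt(abs(cMut@fC - defPrm@fC2), 0.011)
})

test_that("availability factor peaks at intermediate negative supercoiling", {
  expect_equal(availabilityFactor(-40), 1)
  expect_identical(availabilityFactor(c(0, 10, 40)), c(0, 0, 0))
  af <- availabilityFactor(c(-10, -30, -40, -70, -100))
  expect_gt(af[2], af[1])          # interior maximum (generator ground truth)
  expect_gt(af[2], af[3])
  expect_true(all(diff(af[2:5]) < 0))
  expect_lt(0.35 * af[5], 0.03)    # < 3% double peaks at nt = -100
})
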