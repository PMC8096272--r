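# Marko-Siggia worm-like chain: forward model, numeric inverse, fitting.

test_that("WLC force follows the interpolation formula and is monotone", {
  expect_identical(wlcForce(0), 0)
  # half extension: (kT/Lp) * 1.25 (oracle: direct formula evaluation)
  expect_equal(wlcForce(1000, 2000, 46), 4.11 / 46 * 1.25,
               tolerance = 1e-12)
  set.seed(1)
  x <- sort(runif(50, 0, 1999))
  f <- wlcForce(x, 2000, 46)
  expect_true(all(diff(f) > 0))
  expect_error(wlcForce(2000, 2000, 46), "x < L0")
  expect_error(wlcForce(-1, 2000, 46), "0 <= x")
})

test_that("WLC extension inverts the force relation to high precision", {
  expect_identical(wlcExtension(0), 0)
  set.seed(2)
  f <- runif(100, 1e-4, 10)
  x <- wlcExtension(f, 2000, 46)
  expect_lt(max(abs(wlcForce(x, 2000, 46) - f) / f), 1e-9)
  expect_equal(wlcExtension(4.11 / 46 * 1.25, 2000, 46), 1000,
               tolerance = 1e-9)
  expect_error(wlcExtension(-0.1), "force")
})

test_that("WLC fitting recovers parameters and reports uncertainty", {
  forces <- exp(seq(log(0.05), log(3), length.out = 25))
  clean <- data.frame(force_pN = forces,
                      ext_mean_nm = wlcExtension(forces, 2000, 46))
  fit <- fitWLC(clean)
  expect_true(fit$converged)
  expect_lt(abs(fit$L0 - 2000) / 2000, 1e-3)
  expect_lt(abs(fit$Lp - 46) / 46, 1e-3)
  expect_error(fitWLC(clean[1:3, ]), "at least 6")
  # invariance to row order
  set.seed(3)
  noisy <- syntheticWLCCurve(seed = 4)
  shuffled <- noisy[sample(nrow(noisy)), ]
  f1 <- fitWLC(noisy)
  f2 <- fitWLC(shuffled)
  expect_equal(f1$L0, f2$L0, tolerance = 1e-8)
  expect_equal(f1$Lp, f2$Lp, tolerance = 1e-8)
})

test_that("parameter recovery is unbiased at instrument-like noise", {
  set.seed(5)
  L0s <- Lps <- numeric(40)
  for (i in seq_len(40)) {
    fit <- fitWLC(syntheticWLCCurve())
    L0s[i] <- fit$L0
    Lps[i] <- fit$Lp
  }
  expect_lt(abs(median(L0s) - 2000) / 2000, 0.02)
  expect_lt(abs(median(Lps) - 46) / 46, 0.05)
})
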