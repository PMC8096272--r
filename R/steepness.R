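#' @include AllClasses.R
#' @importFrom mclust Mclust mclustBIC
NULL

# Logistic steepness statistics of supercoiled mean force-extension curves
# and Gaussian-mixture analysis of the steepness parameter S0.

#' Generate a synthetic mean curve from the logistic transition model
#'
#' Evaluates `Le = a + b / (1 + exp((F - F1)/S0))` on a force grid and adds
#' Gaussian noise emulating a published ensemble-average curve: per-point
#' ensemble SDs are heteroscedastic (largest in the transition region,
#' smaller on the plateaus) and the averaged curve itself fluctuates by
#' `SD / sqrt(nCurves)`, as for an average over `nCurves` individual
#' force-extension measurements.
#'
#' @param a,b Normalisation constants in nm (for curves increasing with
#'   force `b` is negative and `a` is the high-force plateau).
#' @param F1 Symmetric point of the logistic, pN.
#' @param S0 Steepness parameter, pN (larger = shallower transition).
#' @param forces Force grid, pN.
#' @param baseSd Plateau ensemble SD, nm.
#' @param transSd Additional transition-region ensemble SD, nm.
#' @param nCurves Number of individual curves the synthetic average
#'   emulates (the error bars stay at the ensemble SD; the mean-curve noise
#'   shrinks as `1/sqrt(nCurves)`).
#' @param seed Optional RNG seed.
#' @return Mean-curve data.frame (`force_pN`, `ext_mean_nm`, `ext_sd_nm`,
#'   `n`).
#' @export
syntheticLogisticCurve <- function(a = 1700, b = -1700, F1 = 0.6, S0 = 0.52,
                                   forces = seq(0.05, 3, by = 0.05),
                                   baseSd = 60, transSd = 240,
                                   nCurves = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- stats::plogis((forces - F1) / abs(S0))
  le <- a + b / (1 + exp((forces - F1) / S0))
  sdF <- baseSd + transSd * 4 * q * (1 - q)
  noise <- stats::rnorm(length(forces), 0, sdF / sqrt(nCurves))
  data.frame(force_pN = forces, ext_mean_nm = le + noise,
             ext_sd_nm = sdF, n = as.integer(nCurves))
}

#' Fit the logistic transition model to a mean force-extension curve
#'
#' Least-squares fit of `Le = a + b / (1 + exp((F - F1)/S0))`. The printed
#' functional form is fitted as-is: for curves that increase with force the
#' best fit has `b < 0` (and `a` equal to the high-force plateau); `b`'s
#' sign is reported, not silently flipped. `S0` is constrained positive.
#' Starting values are chosen from the curve orientation (sign of the
#' force-extension correlation), `F1` at the half-range crossing and
#' `S0 = 0.5` pN.
#'
#' @param curve Mean-curve data.frame with `force_pN`, `ext_mean_nm` and
#'   optionally `ext_sd_nm`; at least 8 points bracketing the transition.
#' @param weighted Use `1/sd^2` weights when positive SDs are available
#'   (default `FALSE`: published fits are to ensemble-average curves).
#' @return A list of class `"logisticFit"`: `a`, `b`, `F1`, `S0`, standard
#'   errors (`*.se`), `converged` and the `nls` object `fit`.
#' @examples
#' curve <- syntheticLogisticCurve(seed = 1)
#' fitLogistic(curve)
#' @export
fitLogistic <- function(curve, weighted = FALSE) {
  .checkMeanCurve(curve)
  if (nrow(curve) < 8)
    stop("at least 8 points bracketing the transition are required")
  curve <- curve[order(curve$force_pN), , drop = FALSE]
  ext <- curve$ext_mean_nm
  rng <- range(ext)
  increasing <- stats::cor(curve$force_pN, ext) >= 0
  a0 <- if (increasing) rng[2] else rng[1]
  b0 <- if (increasing) -(rng[2] - rng[1]) else (rng[2] - rng[1])
  F10 <- curve$force_pN[which.min(abs(ext - mean(rng)))]
  w <- rep(1, nrow(curve))
  if (weighted && "ext_sd_nm" %in% names(curve) &&
      all(is.finite(curve$ext_sd_nm)) && all(curve$ext_sd_nm > 0))
    w <- 1 / curve$ext_sd_nm^2
  # fallback F1 start at the steepest part of the curve
  slope <- abs(diff(ext) / diff(curve$force_pN))
  F1g <- curve$force_pN[which.max(slope)]
  starts <- list(list(a = a0, b = b0, F1 = F10, S0 = 0.5),
                 list(a = a0, b = b0, F1 = F10, S0 = 0.1),
                 list(a = a0, b = b0, F1 = F1g, S0 = 0.05))
  # bounds keep the sigmoid anchored to the observed force window and
  # amplitude scale (unbounded fits can drift into a degenerate
  # exponential-tail solution on noisy curves)
  spanE <- max(diff(rng), 1e-6)
  rngF <- range(curve$force_pN)
  spanF <- max(diff(rngF), 1e-6)
  lowerB <- c(a = rng[1] - 2 * spanE, b = -6 * spanE,
              F1 = rngF[1] - 0.5 * spanF, S0 = 1e-4)
  upperB <- c(a = rng[2] + 2 * spanE, b = 6 * spanE,
              F1 = rngF[2] + 0.5 * spanF, S0 = 20)
  res <- NULL
  for (start in starts) {
    res <- tryCatch(
      minpack.lm::nlsLM(
        ext_mean_nm ~ a + b / (1 + exp((force_pN - F1) / S0)),
        data = curve, weights = w, start = start,
        lower = lowerB, upper = upperB,
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) e)
    if (!inherits(res, "error") && res$convInfo$isConv) break
  }
  if (inherits(res, "error")) {
    out <- list(a = NA_real_, b = NA_real_, F1 = NA_real_, S0 = NA_real_,
                a.se = NA_real_, b.se = NA_real_, F1.se = NA_real_,
                S0.se = NA_real_, converged = FALSE,
                message = conditionMessage(res), fit = NULL)
  } else {
    cf <- stats::coef(res)
    se <- tryCatch(sqrt(diag(stats::vcov(res))),
                   error = function(e) rep(NA_real_, 4))
    out <- list(a = unname(cf["a"]), b = unname(cf["b"]),
                F1 = unname(cf["F1"]), S0 = unname(cf["S0"]),
                a.se = unname(se[1]), b.se = unname(se[2]),
                F1.se = unname(se[3]), S0.se = unname(se[4]),
                converged = res$convInfo$isConv, message = "", fit = res)
  }
  class(out) <- "logisticFit"
  out
}

#' @export
print.logisticFit <- function(x, ...) {
  if (!x$converged) {
    cat("Logistic fit: DID NOT CONVERGE -", x$message, "\n")
  } else {
    cat(sprintf(
      "Logistic fit: S0 = %.3f +- %.3f pN, F1 = %.3f pN, a = %.0f, b = %.0f nm\n",
      x$S0, x$S0.se, x$F1, x$a, x$b))
  }
  invisible(x)
}

#' Gaussian-mixture fit of steepness samples
#'
#' Maximum-likelihood Gaussian mixture of the untransformed S0 samples.
#' `k = 1` uses the closed-form normal MLE; `k = 2` fits an
#' unequal-variance univariate mixture by expectation-maximisation
#' (mclust). Components are ordered by mean and relative areas equal the
#' mixture weights. Degenerate near-zero-variance solutions are rejected.
#'
#' @param x Numeric vector of S0 samples, at least 30.
#' @param k Number of components, 1 or 2.
#' @return A list of class `"s0Mixture"`: `k`, `weights`, `means`, `sds`,
#'   `loglik`, `bic` (Schwarz criterion, larger is better), `n`.
#' @export
fitS0Mixture <- function(x, k = 2) {
  stopifnot(is.numeric(x), k %in% c(1, 2))
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 30) stop("at least 30 samples are required")
  if (k == 1) {
    mu <- mean(x)
    sg <- stats::sd(x) * sqrt((n - 1) / n)   # MLE
    ll <- sum(stats::dnorm(x, mu, sg, log = TRUE))
    out <- list(k = 1L, weights = 1, means = mu, sds = sg, loglik = ll,
                bic = 2 * ll - 2 * log(n), n = n)
  } else {
    fit <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
    if (is.null(fit)) stop("mixture fit failed")
    sds <- sqrt(fit$parameters$variance$sigmasq)
    if (any(sds < 1e-10 * stats::sd(x)))
      stop("degenerate zero-variance mixture solution")
    ord <- order(fit$parameters$mean)
    out <- list(k = 2L, weights = fit$parameters$pro[ord],
                means = fit$parameters$mean[ord],
                sds = rep_len(sds, 2)[ord], loglik = fit$loglik,
                bic = fit$bic, n = n)
  }
  class(out) <- "s0Mixture"
  out
}

#' @export
print.s0Mixture <- function(x, ...) {
  cat(sprintf("S0 mixture (k = %d, n = %d): BIC = %.1f\n", x$k, x$n, x$bic))
  for (i in seq_len(x$k))
    cat(sprintf("  component %d: area %.1f%%, mean %.3f, sd %.3f\n",
                i, 100 * x$weights[i], x$means[i], x$sds[i]))
  invisible(x)
}

#' Select between one- and two-component S0 mixtures
#'
#' Fits both models and selects by the Bayesian information criterion;
#' both fits are always returned.
#'
#' @param x Numeric vector of S0 samples.
#' @return List with `k1`, `k2` (the two `"s0Mixture"` fits), `best`
#'   (the selected fit) and `k` (the selected number of components).
#' @export
selectS0Mixture <- function(x) {
  f1 <- fitS0Mixture(x, 1)
  f2 <- tryCatch(fitS0Mixture(x, 2), error = function(e) NULL)
  best <- if (!is.null(f2) && f2$bic > f1$bic) f2 else f1
  list(k1 = f1, k2 = f2, best = best, k = best$k)
}

#' Compare two steepness distributions by the rank-sum test
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test with normal
#' approximation, continuity and tie correction.
#'
#' @param a,b Numeric sample vectors (a warning is issued below 10
#'   observations per group, where the normal approximation is rough).
#' @return An object of class `"htest"` with the rank-sum statistic `W`
#'   (the Mann-Whitney U for the first sample) and the p-value.
#' @export
compareS0Distributions <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) > 0, length(b) > 0)
  if (length(a) < 10 || length(b) < 10)
    warning("fewer than 10 observations per group; ",
            "normal approximation is rough")
  stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE,
                     correct = TRUE)
}
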