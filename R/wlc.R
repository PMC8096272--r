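#' @include constants.R
NULL

# Worm-like-chain elasticity (Marko-Siggia interpolation) and least-squares
# fitting of contour and persistence length from untwisted mean curves.

#' Worm-like-chain force at a given extension
#'
#' Marko-Siggia interpolation formula
#' \deqn{F = \frac{k_B T}{L_p}\left[\frac{1}{4(1 - x/L_0)^2} - \frac14 +
#'   \frac{x}{L_0}\right]}
#' Strictly increasing in `x`, diverging as `x` approaches `L0`.
#'
#' @param x Extension in nm, `0 <= x < L0`.
#' @param L0 Contour length, nm.
#' @param Lp Persistence length, nm.
#' @param temperature Temperature, K.
#' @return Force in pN.
#' @examples
#' wlcForce(0)                    # 0
#' wlcForce(1000, 2000, 46)       # ~0.112 pN at half extension
#' @export
wlcForce <- function(x, L0 = 2000, Lp = 46, temperature = 298) {
  stopifnot(L0 > 0, Lp > 0)
  if (any(x < 0) || any(x >= L0))
    stop("extension must satisfy 0 <= x < L0")
  z <- x / L0
  (kbT(temperature) / Lp) * (1 / (4 * (1 - z)^2) - 0.25 + z)
}

#' Worm-like-chain extension at a given force
#'
#' Numeric inverse of [wlcForce()]. The Marko-Siggia relation reduces to the
#' cubic `4 u^3 + 4 (f - 3/4) u^2 - 1 = 0` in `u = 1 - x/L0` with
#' `f = F Lp / (kB T)`; the unique root in (0, 1] is found by safeguarded
#' Newton iteration to relative tolerance below 1e-12.
#'
#' @param force Force in pN, `>= 0`.
#' @inheritParams wlcForce
#' @return Extension in nm; 0 at zero force.
#' @examples
#' wlcExtension(0)                    # 0
#' wlcExtension(0.112, 2000, 46)      # ~1000 nm
#' @export
wlcExtension <- function(force, L0 = 2000, Lp = 46, temperature = 298) {
  stopifnot(L0 > 0, Lp > 0)
  if (any(force < 0)) stop("force must be >= 0")
  f <- force * Lp / kbT(temperature)
  c3 <- 4
  c2 <- 4 * (f - 0.75)
  g <- function(u) c3 * u^3 + c2 * u^2 - 1
  lo <- rep(0, length(f))
  hi <- rep(1, length(f))        # g(1) = 4 f >= 0, root lies in (0, 1]
  u <- pmin(1, 1 / (2 * sqrt(pmax(f, 0.25))))  # high-force asymptote start
  for (i in 1:200) {
    gu <- g(u)
    conv <- abs(gu) < 1e-12
    if (all(conv)) break
    hi <- ifelse(gu > 0, u, hi)
    lo <- ifelse(gu < 0, u, lo)
    uN <- u - gu / (3 * c3 * u^2 + 2 * c2 * u)
    bad <- !is.finite(uN) | uN <= lo | uN >= hi
    u <- ifelse(conv, u, ifelse(bad, (lo + hi) / 2, uN))
  }
  ext <- L0 * (1 - u)
  ext[force == 0] <- 0
  ext
}

#' Generate a synthetic untwisted mean force-extension curve
#'
#' Emulates an averaged nt = 0 force-extension measurement: the Marko-Siggia
#' WLC curve plus Gaussian noise whose per-point SD follows the thermal
#' fluctuation of the tether, `sqrt(kB T dLe/dF)`, added in quadrature with
#' the tracking resolution. This reproduces the familiar pattern of large
#' error bars at low force shrinking towards the asymptote.
#'
#' @param L0,Lp,temperature Ground-truth WLC parameters.
#' @param forces Force grid in pN (log-spaced by default).
#' @param trackingSd Tracking noise SD in nm.
#' @param seed Optional RNG seed.
#' @return A mean-curve `data.frame` with columns `force_pN`, `ext_mean_nm`,
#'   `ext_sd_nm`, `n`.
#' @export
syntheticWLCCurve <- function(L0 = 2000, Lp = 46, temperature = 298,
                              forces = exp(seq(log(0.05), log(3),
                                               length.out = 30)),
                              trackingSd = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ext <- wlcExtension(forces, L0, Lp, temperature)
  z <- ext / L0
  # dF/dx from the interpolation formula -> fluctuation SD via equipartition
  dFdx <- (kbT(temperature) / (Lp * L0)) * (1 / (2 * (1 - z)^3) + 1)
  sdF <- sqrt(kbT(temperature) / dFdx + trackingSd^2)
  data.frame(force_pN = forces,
             ext_mean_nm = ext + stats::rnorm(length(forces), 0, sdF),
             ext_sd_nm = sdF, n = 1L)
}

.checkMeanCurve <- function(curve) {
  need <- c("force_pN", "ext_mean_nm")
  if (!is.data.frame(curve) || !all(need %in% names(curve)))
    stop("mean curve must be a data.frame with columns force_pN, ext_mean_nm")
  invisible(curve)
}

#' Fit the worm-like-chain model to a mean force-extension curve
#'
#' Weighted least squares in the extension-versus-force direction (the way
#' the data are plotted): `ext_mean_nm ~ wlcExtension(force_pN, L0, Lp)`.
#' Weights are `1/sd^2` when an `ext_sd_nm` column with all-positive values
#' is present and `weighted = TRUE`; otherwise the fit is unweighted.
#'
#' @param curve Mean-curve `data.frame` with columns `force_pN`,
#'   `ext_mean_nm` and optionally `ext_sd_nm`. At least 6 points spanning
#'   the low- and high-force regimes are required.
#' @param weighted Use `1/sd^2` weights when SDs are available.
#' @param temperature Temperature, K.
#' @return A list of class `"wlcFit"`: `L0`, `Lp`, their standard errors
#'   `L0.se`, `Lp.se`, `converged`, and the underlying `nls` object `fit`
#'   (`NULL` on failure, with the error message in `message`).
#' @examples
#' curve <- syntheticWLCCurve(seed = 1)
#' fitWLC(curve)
#' @export
fitWLC <- function(curve, weighted = TRUE, temperature = 298) {
  .checkMeanCurve(curve)
  if (nrow(curve) < 6)
    stop("at least 6 points are required to fit the WLC model")
  curve <- curve[order(curve$force_pN), , drop = FALSE]
  maxExt <- max(curve$ext_mean_nm)
  if (maxExt <= 0) stop("curve has no positive extensions")
  w <- rep(1, nrow(curve))
  if (weighted && "ext_sd_nm" %in% names(curve) &&
      all(is.finite(curve$ext_sd_nm)) && all(curve$ext_sd_nm > 0))
    w <- 1 / curve$ext_sd_nm^2
  start <- list(L0 = 1.05 * maxExt, Lp = 50)
  res <- tryCatch(
    minpack.lm::nlsLM(
      ext_mean_nm ~ wlcExtension(force_pN, L0, Lp, temperature),
      data = curve, start = start, weights = w,
      lower = c(L0 = maxExt * 1e-3, Lp = 1),
      upper = c(L0 = 2 * maxExt, Lp = 200),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(res, "error")) {
    out <- list(L0 = NA_real_, Lp = NA_real_, L0.se = NA_real_,
                Lp.se = NA_real_, converged = FALSE,
                message = conditionMessage(res), fit = NULL)
  } else {
    cf <- stats::coef(res)
    se <- tryCatch(sqrt(diag(stats::vcov(res))),
                   error = function(e) c(NA_real_, NA_real_))
    out <- list(L0 = unname(cf["L0"]), Lp = unname(cf["Lp"]),
                L0.se = unname(se[1]), Lp.se = unname(se[2]),
                converged = res$convInfo$isConv, message = "", fit = res)
  }
  class(out) <- "wlcFit"
  out
}

#' @export
print.wlcFit <- function(x, ...) {
  if (!x$converged) {
    cat("WLC fit: DID NOT CONVERGE -", x$message, "\n")
  } else {
    cat(sprintf("WLC fit: L0 = %.1f +- %.1f nm, Lp = %.1f +- %.1f nm\n",
                x$L0, x$L0.se, x$Lp, x$Lp.se))
  }
  invisible(x)
}
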