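#' @include AllClasses.R constants.R
NULL

# Energy bookkeeping of torsional duplex opening versus G4-assisted opening.

#' Energy cost of relaxing one turn by strand opening
#'
#' \deqn{\alpha = \pi \sqrt{8 B F_C}} with bending constant
#' `B = Lp kB T`. Scales as `sqrt(F_C)`, so the ratio of two alphas depends
#' only on the force ratio.
#'
#' @param fC Characteristic force, pN (`>= 0`).
#' @param Lp Persistence length, nm.
#' @param temperature Temperature, K.
#' @return Energy per relaxed turn in pN nm (convert with
#'   [pNnmToKcalMol()]).
#' @examples
#' alphaPerTurn(0.69)                  # ~101.5 pN nm/turn
#' pNnmToKcalMol(alphaPerTurn(0.69))   # ~14.6 kcal/mol/turn
#' @export
alphaPerTurn <- function(fC, Lp = 46, temperature = 298) {
  if (any(fC < 0)) stop("characteristic force must be >= 0")
  if (Lp <= 0) stop("persistence length must be > 0")
  B <- Lp * kbT(temperature)
  pi * sqrt(8 * B * fC)
}

#' Transition-energy ratio of two characteristic forces
#'
#' `sqrt(fC1 / fC2)`; identical to `alphaPerTurn(fC1) / alphaPerTurn(fC2)`
#' because the bending constant cancels.
#'
#' @param fC1,fC2 Characteristic forces in pN, both `> 0`.
#' @return Dimensionless ratio.
#' @examples
#' energyRatio(0.37, 0.69)   # 0.73
#' @export
energyRatio <- function(fC1, fC2) {
  if (any(fC1 <= 0) || any(fC2 <= 0))
    stop("characteristic forces must be > 0")
  sqrt(fC1 / fC2)
}

#' Duplex versus G4-path opening cost
#'
#' Applies the transition-energy ratio to the duplex opening cost:
#' the G4-assisted path costs `ratio * eDuplex` and the net gain is the
#' difference. Full precision is retained; rounding is for display only.
#'
#' @param eDuplex Duplex opening cost of the G4-forming region, kcal/mol.
#' @param ratio Transition-energy ratio from [energyRatio()], in (0, 1].
#' @return List with `eG4Path` and `netGain` in kcal/mol.
#' @examples
#' g4Ledger(120, energyRatio(0.37, 0.69))   # ~88 and ~32 kcal/mol
#' @export
g4Ledger <- function(eDuplex, ratio) {
  stopifnot(eDuplex > 0, ratio > 0, ratio <= 1)
  list(eG4Path = ratio * eDuplex, netGain = (1 - ratio) * eDuplex)
}

#' Full energy ledger
#'
#' Assembles the per-turn opening energies at the two characteristic
#' forces, the transition-energy ratio, the duplex/G4-path costs and net
#' gain, and (optionally) a measured work area, into a [G4EnergyLedger].
#'
#' @param fC1,fC2 Characteristic forces, pN.
#' @param Lp Persistence length, nm.
#' @param temperature Temperature, K.
#' @param eDuplex Duplex opening cost of the region, kcal/mol.
#' @param perG4Gain Literature folding gain per G4, kcal/mol.
#' @param nG4 Number of G4s in the region.
#' @param workArea Measured work area between cohort mean curves, kcal/mol.
#' @return A [G4EnergyLedger].
#' @examples
#' energyLedger()
#' @export
energyLedger <- function(fC1 = 0.37, fC2 = 0.69, Lp = 46, temperature = 298,
                         eDuplex = 120, perG4Gain = 10, nG4 = 3,
                         workArea = NA_real_) {
  ratio <- energyRatio(fC1, fC2)
  led <- g4Ledger(eDuplex, ratio)
  new("G4EnergyLedger", B = Lp * kbT(temperature), fC1 = fC1, fC2 = fC2,
      alphaC1 = alphaPerTurn(fC1, Lp, temperature),
      alphaC2 = alphaPerTurn(fC2, Lp, temperature), ratio = ratio,
      eDuplex = eDuplex, eG4Path = led$eG4Path, netGain = led$netGain,
      workArea = workArea, perG4Gain = perG4Gain, nG4 = as.integer(nG4))
}

#' Work difference between two mean force-extension curves
#'
#' Trapezoidal integral of `Le_hi - Le_lo` over force (the area between the
#' curves), converted to kcal/mol. When the curves coincide at the ends of
#' the integration range this equals the difference in mechanical work
#' `integral F dLe` between the two extension paths; a warning is issued
#' when the endpoint gap exceeds `endTol` times the maximum curve gap.
#' Positive when `curveHi` lies above `curveLo`.
#'
#' @param curveHi,curveLo Mean-curve data.frames (`force_pN`,
#'   `ext_mean_nm`) on overlapping force ranges; `curveLo` is linearly
#'   interpolated onto `curveHi`'s grid.
#' @param fRange Optional integration range `c(min, max)` in pN.
#' @param endTol Endpoint coincidence tolerance (fraction of the maximum
#'   absolute gap).
#' @return Area in kcal/mol, with the raw pN nm value in attribute
#'   `"pNnm"`.
#' @examples
#' hi <- data.frame(force_pN = seq(0, 2, 0.1), ext_mean_nm = 100)
#' lo <- data.frame(force_pN = seq(0, 2, 0.1), ext_mean_nm = 0)
#' workArea(hi, lo, fRange = c(0.5, 1.5))   # 100 pN nm = 14.4 kcal/mol
#' @export
workArea <- function(curveHi, curveLo, fRange = NULL, endTol = 0.05) {
  .checkMeanCurve(curveHi)
  .checkMeanCurve(curveLo)
  lo <- range(curveHi$force_pN)
  lo2 <- range(curveLo$force_pN)
  from <- max(lo[1], lo2[1])
  to <- min(lo[2], lo2[2])
  if (!is.null(fRange)) {
    from <- max(from, fRange[1])
    to <- min(to, fRange[2])
  }
  if (from >= to) stop("force ranges do not overlap")
  keep <- curveHi$force_pN >= from & curveHi$force_pN <= to
  f <- curveHi$force_pN[keep]
  if (length(f) < 2) stop("fewer than 2 points in the integration range")
  hi <- curveHi$ext_mean_nm[keep]
  loI <- stats::approx(curveLo$force_pN, curveLo$ext_mean_nm, xout = f,
                       rule = 2)$y
  delta <- hi - loI
  maxGap <- max(abs(delta))
  if (maxGap > 0 &&
      max(abs(delta[1]), abs(delta[length(delta)])) > endTol * maxGap)
    warning("curves do not coincide at the integration-range ends; ",
            "the area is not a pure work difference")
  areaPNnm <- pracma::trapz(f, delta)
  out <- pNnmToKcalMol(areaPNnm)
  attr(out, "pNnm") <- areaPNnm
  out
}

#' Supercoiling density
#'
#' `sigma = nT / (Nb / helicalRepeat)`: imposed turns normalised by the
#' tether's natural number of helical turns.
#'
#' @param nT Imposed turns (signed).
#' @param Nb Number of base pairs, `> 0`.
#' @param helicalRepeat Helical repeat, bp/turn.
#' @return Dimensionless supercoiling density.
#' @examples
#' supercoilDensity(-40, 6680)   # -0.0623
#' supercoilDensity(-40, 5943)   # -0.070
#' @export
supercoilDensity <- function(nT, Nb, helicalRepeat = 10.4) {
  if (any(Nb <= 0)) stop("Nb must be > 0")
  nT * helicalRepeat / Nb
}
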