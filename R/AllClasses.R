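#' @include constants.R
NULL

.CONSTRUCTS <- c("wt", "mut")
.IONS <- c("KCl", "NaCl", "LiCl")

# Double-peak occurrence rates per (construct, ion), calibrated to the
# published ensemble percentages at the reference supercoiling (nt = -40).
.P_FOLD_TABLE <- c("wt.KCl" = 0.35, "wt.NaCl" = 0.18, "wt.LiCl" = 0.11,
                   "mut.KCl" = 0.12, "mut.NaCl" = 0.12, "mut.LiCl" = 0.12)

# ---------------------------------------------------------------------------
# TetherConfig
# ---------------------------------------------------------------------------

#' Tether configuration
#'
#' Describes a torsionally constrained DNA tether: construct identity
#' (`wt` carries the intact G4-forming promoter region, `mut` the
#' folding-incompetent point-mutated version), monovalent ion, geometry and
#' the per-ramp probability that the G4 pathway is available.
#'
#' @slot construct `"wt"` or `"mut"`.
#' @slot ion `"KCl"`, `"NaCl"` or `"LiCl"`.
#' @slot nBasepairs Tether length in base pairs.
#' @slot contourLength Contour length in nm.
#' @slot persistenceLength Persistence length in nm.
#' @slot g4RegionBp Length of the G4-forming region in bp.
#' @slot nG4 Number of distinct G4 motifs in the region.
#' @slot helicalRepeat Helical repeat in bp per turn.
#' @slot pFold Per-ramp probability that the G4 pathway is available at the
#'   reference supercoiling (nt = -40).
#' @slot temperature Temperature in K.
#' @export
setClass("TetherConfig",
  representation(construct = "character", ion = "character",
                 nBasepairs = "integer", contourLength = "numeric",
                 persistenceLength = "numeric", g4RegionBp = "integer",
                 nG4 = "integer", helicalRepeat = "numeric",
                 pFold = "numeric", temperature = "numeric"))

setValidity("TetherConfig", function(object) {
  msg <- character()
  if (!object@construct %in% .CONSTRUCTS)
    msg <- c(msg, "construct must be 'wt' or 'mut'")
  if (!object@ion %in% .IONS)
    msg <- c(msg, "ion must be one of 'KCl', 'NaCl', 'LiCl'")
  if (object@contourLength <= 0) msg <- c(msg, "contourLength must be > 0")
  if (object@persistenceLength <= 0)
    msg <- c(msg, "persistenceLength must be > 0")
  if (object@g4RegionBp >= object@nBasepairs)
    msg <- c(msg, "g4RegionBp must be < nBasepairs")
  if (is.na(object@pFold) || object@pFold < 0 || object@pFold > 1)
    msg <- c(msg, "pFold must lie in [0, 1]")
  if (object@helicalRepeat <= 0) msg <- c(msg, "helicalRepeat must be > 0")
  if (object@temperature <= 0) msg <- c(msg, "temperature must be > 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn TetherConfig Constructor. When `pFold` is `NA` it is looked up
#'   from the calibrated (construct, ion) table: wt 0.35/0.18/0.11 in
#'   KCl/NaCl/LiCl and mut 0.12 (ion independent).
#' @param construct,ion,nBasepairs,contourLength,persistenceLength,g4RegionBp,nG4,helicalRepeat,pFold,temperature
#'   See slot descriptions.
#' @return A `TetherConfig` object.
#' @examples
#' TetherConfig()                      # wt in KCl, pFold 0.35
#' TetherConfig("mut", "KCl")          # pFold 0.12
#' @export
TetherConfig <- function(construct = "wt", ion = "KCl", nBasepairs = 6680L,
                         contourLength = 2000, persistenceLength = 46,
                         g4RegionBp = 72L, nG4 = 3L, helicalRepeat = 10.4,
                         pFold = NA_real_, temperature = 298) {
  construct <- match.arg(construct, .CONSTRUCTS)
  ion <- match.arg(ion, .IONS)
  if (is.na(pFold))
    pFold <- unname(.P_FOLD_TABLE[paste(construct, ion, sep = ".")])
  new("TetherConfig", construct = construct, ion = ion,
      nBasepairs = as.integer(nBasepairs), contourLength = contourLength,
      persistenceLength = persistenceLength,
      g4RegionBp = as.integer(g4RegionBp), nG4 = as.integer(nG4),
      helicalRepeat = helicalRepeat, pFold = pFold, temperature = temperature)
}

setMethod("show", "TetherConfig", function(object) {
  cat("TetherConfig:", object@construct, "in", object@ion, "\n")
  cat(sprintf("  %d bp, L0 = %g nm, Lp = %g nm, %d bp G4 region (%d G4s)\n",
              object@nBasepairs, object@contourLength,
              object@persistenceLength, object@g4RegionBp, object@nG4))
  cat(sprintf("  pFold = %.3f, helical repeat = %g bp/turn, T = %g K\n",
              object@pFold, object@helicalRepeat, object@temperature))
})

# ---------------------------------------------------------------------------
# SimParams
# ---------------------------------------------------------------------------

#' Trace simulation parameters
#'
#' Parameters of the phenomenological three-state generator: the two
#' characteristic forces (centres of the sequential plectoneme-to-G4 and
#' G4-to-bubble logistics), transition width, plectoneme extension slope,
#' hopping and bead-relaxation kinetics, noise amplitudes and acquisition
#' settings.
#'
#' @slot fC1 Lower characteristic force (G4 sub-transition centre), pN.
#' @slot fC2 Upper characteristic force (plectoneme/bubble transition), pN.
#' @slot turnsPerG4 Turns absorbed when the G4 region opens (72/10.4 by
#'   default: the whole promoter region opens as one event).
#' @slot plectonemeSlope Extension lost per plectonemic turn, nm/turn.
#' @slot transitionWidth Logistic width of both transitions, pN.
#' @slot hopRateScale Multiplier on the base pair-hopping rate (20 / s).
#' @slot relaxTime Bead mean-reversion time constant, s.
#' @slot beadNoiseSd Stationary SD of the Ornstein-Uhlenbeck bead noise, nm.
#' @slot trackingNoiseSd SD of the white tracking noise, nm (axial
#'   resolution of the instrument).
#' @slot sampleRate Acquisition rate, Hz.
#' @slot dwell Acquisition time per force, s.
#' @export
setClass("SimParams",
  representation(fC1 = "numeric", fC2 = "numeric", turnsPerG4 = "numeric",
                 plectonemeSlope = "numeric", transitionWidth = "numeric",
                 hopRateScale = "numeric", relaxTime = "numeric",
                 beadNoiseSd = "numeric", trackingNoiseSd = "numeric",
                 sampleRate = "numeric", dwell = "numeric"))

setValidity("SimParams", function(object) {
  msg <- character()
  if (!is.finite(object@fC1) || !is.finite(object@fC2))
    msg <- c(msg, "characteristic forces must be finite")
  if (object@fC1 >= object@fC2) msg <- c(msg, "fC1 must be < fC2")
  if (object@fC1 < 0) msg <- c(msg, "fC1 must be >= 0")
  if (object@transitionWidth <= 0) msg <- c(msg, "transitionWidth must be > 0")
  if (object@plectonemeSlope <= 0) msg <- c(msg, "plectonemeSlope must be > 0")
  if (object@turnsPerG4 <= 0) msg <- c(msg, "turnsPerG4 must be > 0")
  if (object@hopRateScale <= 0) msg <- c(msg, "hopRateScale must be > 0")
  if (object@relaxTime <= 0) msg <- c(msg, "relaxTime must be > 0")
  if (object@beadNoiseSd < 0 || object@trackingNoiseSd < 0)
    msg <- c(msg, "noise SDs must be >= 0")
  if (object@dwell * object@sampleRate < 2)
    msg <- c(msg, "dwell * sampleRate must be >= 2")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimParams Constructor with calibrated defaults. The default
#'   `plectonemeSlope` (75 nm/turn) sets the programmed G4 work gain,
#'   `turnsPerG4 * plectonemeSlope * (fC2 - fC1)`, to ~24 kcal/mol.
#' @param fC1,fC2,turnsPerG4,plectonemeSlope,transitionWidth,hopRateScale,relaxTime,beadNoiseSd,trackingNoiseSd,sampleRate,dwell
#'   See slot descriptions.
#' @return A `SimParams` object.
#' @examples
#' SimParams()
#' SimParams(fC1 = 0.30, transitionWidth = 0.05)
#' @export
SimParams <- function(fC1 = 0.37, fC2 = 0.69, turnsPerG4 = 72 / 10.4,
                      plectonemeSlope = 75, transitionWidth = 0.035,
                      hopRateScale = 1, relaxTime = 0.05, beadNoiseSd = 15,
                      trackingNoiseSd = 10, sampleRate = 300, dwell = 5) {
  new("SimParams", fC1 = fC1, fC2 = fC2, turnsPerG4 = turnsPerG4,
      plectonemeSlope = plectonemeSlope, transitionWidth = transitionWidth,
      hopRateScale = hopRateScale, relaxTime = relaxTime,
      beadNoiseSd = beadNoiseSd, trackingNoiseSd = trackingNoiseSd,
      sampleRate = sampleRate, dwell = dwell)
}

setMethod("show", "SimParams", function(object) {
  cat("SimParams:\n")
  cat(sprintf("  fC1 = %g pN, fC2 = %g pN, width = %g pN\n",
              object@fC1, object@fC2, object@transitionWidth))
  cat(sprintf("  plectoneme slope = %g nm/turn, turns per G4 event = %.2f\n",
              object@plectonemeSlope, object@turnsPerG4))
  cat(sprintf("  hop rate scale = %g, relax time = %g s\n",
              object@hopRateScale, object@relaxTime))
  cat(sprintf("  bead / tracking noise = %g / %g nm, %g Hz, dwell %g s\n",
              object@beadNoiseSd, object@trackingNoiseSd,
              object@sampleRate, object@dwell))
})

# ---------------------------------------------------------------------------
# Trace
# ---------------------------------------------------------------------------

#' Extension time series at one (force, turns) set point
#'
#' @slot force Applied force, pN.
#' @slot turns Imposed turns (signed integer).
#' @slot time Time stamps in s, uniform step `1/sampleRate`.
#' @slot extension End-to-end extension in nm.
#' @slot meta Provenance list (config, params, seed, g4Available).
#' @export
setClass("Trace",
  representation(force = "numeric", turns = "numeric", time = "numeric",
                 extension = "numeric", meta = "list"))

setValidity("Trace", function(object) {
  msg <- character()
  if (length(object@time) != length(object@extension))
    msg <- c(msg, "time and extension must have equal length")
  if (length(object@time) > 1) {
    dt <- diff(object@time)
    if (any(dt <= 0)) msg <- c(msg, "time must be strictly increasing")
    if (diff(range(dt)) > 1e-9 * mean(dt))
      msg <- c(msg, "time step must be uniform")
  }
  if (!all(is.finite(object@extension)))
    msg <- c(msg, "extension must be finite")
  if (object@force < 0) msg <- c(msg, "force must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Trace", function(object) {
  cat(sprintf("Trace: %d samples at F = %g pN, nt = %g\n",
              length(object@time), object@force, object@turns))
  if (length(object@extension))
    cat(sprintf("  extension mean %.1f nm, var %.1f nm^2\n",
                mean(object@extension), stats::var(object@extension)))
})

# ---------------------------------------------------------------------------
# ForceRamp
# ---------------------------------------------------------------------------

#' Ordered set of traces over a force grid at fixed turns
#'
#' @slot traces List of [Trace] objects, one per grid force.
#' @slot forceGrid Strictly increasing force grid, pN.
#' @slot turns Shared imposed turns.
#' @slot g4Available Whether the G4 pathway is available on this ramp
#'   (generator ground truth).
#' @slot config The [TetherConfig] used.
#' @slot params The [SimParams] used.
#' @export
setClass("ForceRamp",
  representation(traces = "list", forceGrid = "numeric", turns = "numeric",
                 g4Available = "logical", config = "TetherConfig",
                 params = "SimParams"))

setValidity("ForceRamp", function(object) {
  msg <- character()
  if (length(object@traces) != length(object@forceGrid))
    msg <- c(msg, "one trace per grid force required")
  if (length(object@forceGrid) < 1) msg <- c(msg, "force grid must be non-empty")
  if (any(diff(object@forceGrid) <= 0))
    msg <- c(msg, "force grid must be strictly increasing")
  trTurns <- vapply(object@traces, function(t) t@turns, numeric(1))
  if (length(trTurns) && any(trTurns != object@turns))
    msg <- c(msg, "all traces must share the ramp's turns")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ForceRamp", function(object) {
  cat(sprintf("ForceRamp: %d traces, F in [%g, %g] pN, nt = %g\n",
              length(object@traces), min(object@forceGrid),
              max(object@forceGrid), object@turns))
  cat(sprintf("  %s in %s, G4 pathway %savailable\n",
              object@config@construct, object@config@ion,
              if (object@g4Available) "" else "not "))
})

# ---------------------------------------------------------------------------
# VarianceProfile
# ---------------------------------------------------------------------------

#' Extension variance as a function of force
#'
#' The object that is peak-classified: per-force unbiased sample variance of
#' the extension over an analysis window, plus the per-force mean extension
#' (used for cohort mean curves).
#'
#' @slot force Force grid, pN.
#' @slot variance Extension variance, nm^2.
#' @slot meanExtension Mean extension per force, nm.
#' @slot window Analysis window, s.
#' @slot turns Imposed turns.
#' @slot meta Provenance list.
#' @export
setClass("VarianceProfile",
  representation(force = "numeric", variance = "numeric",
                 meanExtension = "numeric", window = "numeric",
                 turns = "numeric", meta = "list"))

setValidity("VarianceProfile", function(object) {
  msg <- character()
  if (length(object@force) != length(object@variance))
    msg <- c(msg, "force and variance must have equal length")
  if (any(object@variance < 0)) msg <- c(msg, "variance must be >= 0")
  if (length(object@force) > 1 && any(diff(object@force) <= 0))
    msg <- c(msg, "force must be strictly increasing")
  if (object@window <= 0) msg <- c(msg, "window must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "VarianceProfile", function(object) {
  cat(sprintf("VarianceProfile: %d forces in [%g, %g] pN, window %g s, nt = %g\n",
              length(object@force), min(object@force), max(object@force),
              object@window, object@turns))
  cat(sprintf("  max variance %.0f nm^2 at %g pN\n",
              max(object@variance), object@force[which.max(object@variance)]))
})

# ---------------------------------------------------------------------------
# PeakClassification
# ---------------------------------------------------------------------------

#' Single/double/no-peak call on a variance profile
#'
#' @slot label One of `"no_peak"`, `"single"`, `"double"`.
#' @slot fC Characteristic force for a single peak, pN (NA otherwise).
#' @slot fC1,fC2 Ordered characteristic forces for a double peak, pN.
#' @slot deltaF `fC2 - fC1`, pN (NA unless double).
#' @slot peaks data.frame of all retained maxima (force, height, prominence).
#' @slot options Detection options used (smoothing SD, prominence fraction,
#'   minimum separation, window).
#' @export
setClass("PeakClassification",
  representation(label = "character", fC = "numeric", fC1 = "numeric",
                 fC2 = "numeric", deltaF = "numeric", peaks = "data.frame",
                 options = "list"))

setValidity("PeakClassification", function(object) {
  msg <- character()
  if (!object@label %in% c("no_peak", "single", "double"))
    msg <- c(msg, "label must be no_peak, single or double")
  if (object@label == "double" &&
      !(is.finite(object@fC1) && is.finite(object@fC2) &&
        object@fC1 < object@fC2))
    msg <- c(msg, "double classification requires fC1 < fC2")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PeakClassification", function(object) {
  switch(object@label,
    no_peak = cat("PeakClassification: no peak\n"),
    single = cat(sprintf("PeakClassification: single peak, F_C = %g pN\n",
                         object@fC)),
    double = cat(sprintf(
      "PeakClassification: double peak, F_C1 = %g pN, F_C2 = %g pN (dF = %g)\n",
      object@fC1, object@fC2, object@deltaF)))
  if (nrow(object@peaks))
    cat(sprintf("  %d retained maxima\n", nrow(object@peaks)))
})

# ---------------------------------------------------------------------------
# EnsembleSummary
# ---------------------------------------------------------------------------

#' Ensemble statistics of peak classifications
#'
#' @slot n Number of ramps.
#' @slot nDouble,nSingle,nNone Counts per label.
#' @slot pctDouble Percentage of double-peak calls.
#' @slot sePct Binomial standard error of `pctDouble` in percentage points,
#'   `100 * sqrt(p (1 - p) / n)`.
#' @slot fcStats data.frame of characteristic-force mean/SD per peak class.
#' @slot meta Provenance list.
#' @export
setClass("EnsembleSummary",
  representation(n = "integer", nDouble = "integer", nSingle = "integer",
                 nNone = "integer", pctDouble = "numeric", sePct = "numeric",
                 fcStats = "data.frame", meta = "list"))

setMethod("show", "EnsembleSummary", function(object) {
  cat(sprintf("EnsembleSummary: n = %d ramps\n", object@n))
  cat(sprintf("  double %d (%.1f%% +- %.1f), single %d, none %d\n",
              object@nDouble, object@pctDouble, object@sePct,
              object@nSingle, object@nNone))
  if (nrow(object@fcStats)) {
    for (i in seq_len(nrow(object@fcStats)))
      cat(sprintf("  %-10s mean %.3f pN, sd %.3f pN (n = %d)\n",
                  object@fcStats$which[i], object@fcStats$mean[i],
                  object@fcStats$sd[i], object@fcStats$n[i]))
  }
})

# ---------------------------------------------------------------------------
# G4EnergyLedger
# ---------------------------------------------------------------------------

#' Energy bookkeeping of duplex opening versus G4-assisted opening
#'
#' Collects the per-turn opening energies at the two characteristic forces,
#' the transition-energy ratio, the duplex opening cost and the cost/gain of
#' the G4-assisted path, together with the measured work area when available.
#'
#' @slot B Bending constant Lp * kB * T, pN nm^2.
#' @slot fC1,fC2 Characteristic forces, pN.
#' @slot alphaC1,alphaC2 Energy per relaxed turn at fC1/fC2, pN nm.
#' @slot ratio Transition-energy ratio sqrt(fC1/fC2).
#' @slot eDuplex Reference duplex opening cost, kcal/mol.
#' @slot eG4Path Cost along the G4-assisted path, kcal/mol.
#' @slot netGain `eDuplex - eG4Path`, kcal/mol.
#' @slot workArea Measured work area between cohort mean curves, kcal/mol
#'   (NA when not computed).
#' @slot perG4Gain,nG4 Literature per-G4 folding gain (kcal/mol) and number
#'   of G4s, for the consistency cross-check.
#' @export
setClass("G4EnergyLedger",
  representation(B = "numeric", fC1 = "numeric", fC2 = "numeric",
                 alphaC1 = "numeric", alphaC2 = "numeric", ratio = "numeric",
                 eDuplex = "numeric", eG4Path = "numeric", netGain = "numeric",
                 workArea = "numeric", perG4Gain = "numeric", nG4 = "integer"))

setValidity("G4EnergyLedger", function(object) {
  msg <- character()
  if (any(c(object@alphaC1, object@alphaC2, object@eDuplex,
            object@eG4Path) < 0, na.rm = TRUE))
    msg <- c(msg, "energies must be >= 0")
  if (is.finite(object@ratio) && (object@ratio <= 0 || object@ratio > 1))
    msg <- c(msg, "ratio must lie in (0, 1] when fC1 <= fC2")
  if (length(msg)) msg else TRUE
})

setMethod("show", "G4EnergyLedger", function(object) {
  s2 <- function(x) signif(x, 2)   # 2 significant figures for display only
  cat("G4 energy ledger\n")
  cat(sprintf("  F_C1 = %g pN, F_C2 = %g pN, B = %.1f pN nm^2\n",
              object@fC1, object@fC2, object@B))
  cat(sprintf("  alpha(F_C1) = %g pN nm/turn (%g kcal/mol/turn)\n",
              s2(object@alphaC1), s2(pNnmToKcalMol(object@alphaC1))))
  cat(sprintf("  alpha(F_C2) = %g pN nm/turn (%g kcal/mol/turn)\n",
              s2(object@alphaC2), s2(pNnmToKcalMol(object@alphaC2))))
  cat(sprintf("  transition-energy ratio sqrt(F_C1/F_C2) = %.2f\n",
              object@ratio))
  cat(sprintf("  duplex opening cost   %g kcal/mol\n", s2(object@eDuplex)))
  cat(sprintf("  G4-assisted path cost %g kcal/mol\n", s2(object@eG4Path)))
  cat(sprintf("  net gain              %g kcal/mol\n", s2(object@netGain)))
  cat(sprintf("  expected %d x %g kcal/mol per G4 = %g kcal/mol\n",
              object@nG4, object@perG4Gain,
              s2(object@nG4 * object@perG4Gain)))
  if (is.finite(object@workArea))
    cat(sprintf("  measured work area    %g kcal/mol\n", s2(object@workArea)))
})
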