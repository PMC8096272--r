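#' @include AllClasses.R wlc.R
NULL

# Phenomenological three-state generator for magnetic-tweezers-like traces:
# plectonemic (P), G4 intermediate (G) and denaturation-bubble (D) states with
# sequential logistic occupancies centred at the two characteristic forces,
# telegraph hopping between adjacent states, Ornstein-Uhlenbeck bead noise
# and white tracking noise.

.BASE_HOP_RATE <- 20   # 1/s; pair hopping rate at hopRateScale = 1

#' Default force grid of a ramp
#'
#' @param from,to,by Grid limits and step in pN (0.05 to 3.0 in 0.01 pN
#'   steps by default, 296 forces).
#' @return Numeric vector of forces.
#' @export
defaultForceGrid <- function(from = 0.05, to = 3, by = 0.01) {
  seq(from, to, by = by)
}

.stateExtensions <- function(force, nT, cfg, prm) {
  leD <- wlcExtension(force, cfg@contourLength, cfg@persistenceLength,
                      cfg@temperature)
  leP <- pmax(0, leD - prm@plectonemeSlope * abs(nT))
  leG <- leP + prm@plectonemeSlope * prm@turnsPerG4
  cbind(P = leP, G = leG, D = leD)
}

#' State occupancies of the three-state transition model
#'
#' Sequential two-logistic occupancy model. Under negative supercoiling the
#' plectonemic state converts at `fC1` into the G4 intermediate (promoter
#' region opened and folded, absorbing `turnsPerG4` turns) and at `fC2` into
#' the denaturation-bubble state. When the G4 pathway is unavailable the
#' P-to-D conversion is a single logistic centred at `fC2`. For `nT >= 0`
#' duplex opening does not occur and the plectonemic state has occupancy 1.
#'
#' @param force Force(s) in pN, `>= 0`.
#' @param nT Imposed turns (negative for the transition model).
#' @param cfg A [TetherConfig].
#' @param prm A [SimParams].
#' @param g4Available Logical: is the G4 pathway available on this ramp?
#' @return Matrix with one row per force and columns `P`, `G`, `D`;
#'   occupancies are non-negative and sum to 1.
#' @examples
#' stateOccupancies(0.37, -40, TetherConfig(), SimParams(), TRUE)
#' stateOccupancies(0.69, -40, TetherConfig(), SimParams(), FALSE)
#' @export
stateOccupancies <- function(force, nT, cfg = TetherConfig(),
                             prm = SimParams(), g4Available = TRUE) {
  if (any(force < 0)) stop("force must be >= 0")
  if (prm@transitionWidth <= 0) stop("transition width must be > 0")
  n <- length(force)
  if (nT >= 0)
    return(cbind(P = rep(1, n), G = rep(0, n), D = rep(0, n)))
  w <- prm@transitionWidth
  q2 <- stats::plogis((force - prm@fC2) / w)
  if (g4Available) {
    q1 <- stats::plogis((force - prm@fC1) / w)
    cbind(P = 1 - q1, G = q1 * (1 - q2), D = q1 * q2)
  } else {
    cbind(P = 1 - q2, G = rep(0, n), D = q2)
  }
}

#' Mean extension of the three-state model
#'
#' Occupancy-weighted extension
#' `p_P Le_P + p_G Le_G + p_D Le_D`, where `Le_D` is the WLC extension at
#' the applied force, `Le_P = max(0, Le_D - slope |nT|)` is the
#' plectoneme-shortened extension and `Le_G = Le_P + slope * turnsPerG4`
#' reflects the turns relaxed by opening the G4 region.
#'
#' @inheritParams stateOccupancies
#' @return Mean extension(s) in nm; monotone non-decreasing in force.
#' @export
meanExtension <- function(force, nT, cfg = TetherConfig(), prm = SimParams(),
                          g4Available = TRUE) {
  occ <- stateOccupancies(force, nT, cfg, prm, g4Available)
  le <- .stateExtensions(force, nT, cfg, prm)
  rowSums(occ * le)
}

#' State-mixing variance of the three-state model (noiseless limit)
#'
#' Closed-form variance of the state-hopping process,
#' `sum_i p_i Le_i^2 - (sum_i p_i Le_i)^2`. This is the noiseless-limit
#' variance profile: the long-window trace variance equals it plus the
#' bead and tracking noise floor.
#'
#' @inheritParams stateOccupancies
#' @return Mixing variance(s) in nm^2.
#' @export
mixingVariance <- function(force, nT, cfg = TetherConfig(), prm = SimParams(),
                           g4Available = TRUE) {
  occ <- stateOccupancies(force, nT, cfg, prm, g4Available)
  le <- .stateExtensions(force, nT, cfg, prm)
  # clamp tiny negative values from floating-point cancellation
  pmax(0, rowSums(occ * le^2) - rowSums(occ * le)^2)
}

#' Generator availability factor versus supercoiling
#'
#' Phenomenological modulation of the per-ramp G4-availability probability
#' with the imposed turns: a denaturation-bubble opening factor grows with
#' `|nT|` (more melted base pairs reach the promoter) while a
#' plectoneme-occlusion factor suppresses availability at strong
#' supercoiling (plectonemes hide the promoter region). The factor is
#' normalised to 1 at the reference `nT = -40`, so `pFold` retains its
#' calibrated meaning there; it is zero for `nT >= 0` (no duplex opening).
#' This is generator behaviour, not an inference from data.
#'
#' @param nT Imposed turns (vectorised).
#' @param nOpen Turn scale of bubble opening (default 15).
#' @param nOcc Onset of plectoneme occlusion in turns (default 30).
#' @param nScale Decay scale of occlusion in turns (default 22).
#' @return Multiplicative factor on `pFold` (1 at nT = -40); the factor
#'   peaks at an intermediate negative supercoiling (~ -30 turns).
#' @export
availabilityFactor <- function(nT, nOpen = 15, nOcc = 30, nScale = 22) {
  g <- function(n) (1 - exp(-n / nOpen)) * exp(-pmax(0, n - nOcc) / nScale)
  out <- ifelse(nT >= 0, 0, g(abs(nT)) / g(40))
  unname(out)
}

# Continuous-time telegraph over the active states of a linear chain
# (P <-> G <-> D), with pair rates satisfying detailed balance with respect
# to the target occupancies. Returns the state index (1..3) at each sample.
.telegraphStates <- function(p, k0, nSamp, dt) {
  active <- which(p > 1e-12)
  if (length(active) == 1L) return(rep.int(active, nSamp))
  pa <- p[active]
  m <- length(active)
  up <- numeric(m)
  down <- numeric(m)
  for (i in seq_len(m - 1L)) {
    tot <- pa[i] + pa[i + 1L]
    up[i] <- k0 * pa[i + 1L] / tot
    down[i + 1L] <- k0 * pa[i] / tot
  }
  tEnd <- nSamp * dt
  cap <- 256L
  evT <- numeric(cap)
  evS <- integer(cap)
  s <- sample.int(m, 1L, prob = pa)
  evT[1L] <- 0
  evS[1L] <- s
  nEv <- 1L
  t <- 0
  repeat {
    rUp <- up[s]
    rDn <- down[s]
    rTot <- rUp + rDn
    if (rTot <= 0) break
    t <- t + stats::rexp(1L, rTot)
    if (t >= tEnd) break
    s <- if (stats::runif(1L) < rUp / rTot) s + 1L else s - 1L
    nEv <- nEv + 1L
    if (nEv > cap) {
      evT <- c(evT, numeric(cap))
      evS <- c(evS, integer(cap))
      cap <- 2L * cap
    }
    evT[nEv] <- t
    evS[nEv] <- s
  }
  idx <- findInterval((seq_len(nSamp) - 1L) * dt, evT[seq_len(nEv)])
  active[evS[idx]]
}

# One extension time series at fixed (force, turns); consumes the current
# RNG stream. `le` and `occ` are the precomputed levels/occupancies row.
.simulateExtensionRow <- function(le, occ, prm) {
  nSamp <- as.integer(round(prm@dwell * prm@sampleRate))
  dt <- 1 / prm@sampleRate
  st <- .telegraphStates(occ, .BASE_HOP_RATE * prm@hopRateScale, nSamp, dt)
  ext <- unname(le[st])
  if (prm@beadNoiseSd > 0) {
    rho <- exp(-dt / prm@relaxTime)
    inn <- stats::rnorm(nSamp, 0, prm@beadNoiseSd * sqrt(1 - rho^2))
    ext <- ext + as.numeric(stats::filter(inn, rho, method = "recursive",
                                          init = stats::rnorm(1, 0, prm@beadNoiseSd)))
  }
  if (prm@trackingNoiseSd > 0)
    ext <- ext + stats::rnorm(nSamp, 0, prm@trackingNoiseSd)
  ext
}

.simulateExtension <- function(force, nT, cfg, prm, g4Available) {
  if (!all(is.finite(c(force, nT)))) stop("non-finite simulation inputs")
  occ <- stateOccupancies(force, nT, cfg, prm, g4Available)[1L, ]
  le <- .stateExtensions(force, nT, cfg, prm)[1L, ]
  .simulateExtensionRow(le, occ, prm)
}

#' Simulate one extension trace
#'
#' Generates a stationary extension time series at fixed force and imposed
#' turns: telegraph hopping between the occupied states (detailed-balance
#' rates, base pair rate 20/s x `hopRateScale`), additive mean-reverting
#' bead noise (OU, time constant `relaxTime`) and white tracking noise. The
#' long-window variance equals the closed-form [mixingVariance()] plus the
#' noise floor `beadNoiseSd^2 + trackingNoiseSd^2`.
#'
#' @inheritParams stateOccupancies
#' @param force Single force in pN.
#' @param seed Optional RNG seed (identical seeds give identical traces).
#' @return A [Trace].
#' @examples
#' tr <- simulateTrace(0.69, -40, g4Available = FALSE, seed = 1)
#' tr
#' @export
simulateTrace <- function(force, nT, cfg = TetherConfig(), prm = SimParams(),
                          g4Available = TRUE, seed = NULL) {
  stopifnot(length(force) == 1L)
  if (!is.null(seed)) set.seed(seed)
  ext <- .simulateExtension(force, nT, cfg, prm, g4Available)
  nSamp <- length(ext)
  new("Trace", force = force, turns = nT,
      time = (seq_len(nSamp) - 1L) / prm@sampleRate, extension = ext,
      meta = list(config = cfg, params = prm, g4Available = g4Available,
                  seed = if (is.null(seed)) NA_integer_ else seed))
}

#' Simulate a force ramp
#'
#' One trace per grid force at fixed imposed turns, drawn from a single
#' RNG stream spawned by `seed` (the G4-availability flag is constant
#' across the whole ramp).
#'
#' @inheritParams simulateTrace
#' @param forceGrid Strictly increasing force grid in pN.
#' @return A [ForceRamp].
#' @export
simulateRamp <- function(nT, cfg = TetherConfig(), prm = SimParams(),
                         g4Available = TRUE, forceGrid = defaultForceGrid(),
                         seed = NULL) {
  if (length(forceGrid) < 1) stop("force grid must be non-empty")
  if (any(diff(forceGrid) <= 0)) stop("force grid must be strictly increasing")
  if (!is.null(seed)) set.seed(seed)
  occ <- stateOccupancies(forceGrid, nT, cfg, prm, g4Available)
  le <- .stateExtensions(forceGrid, nT, cfg, prm)
  tVec <- (seq_len(as.integer(round(prm@dwell * prm@sampleRate))) - 1L) /
    prm@sampleRate
  trs <- lapply(seq_along(forceGrid), function(i) {
    new("Trace", force = forceGrid[i], turns = nT, time = tVec,
        extension = .simulateExtensionRow(le[i, ], occ[i, ], prm),
        meta = list(g4Available = g4Available))
  })
  new("ForceRamp", traces = trs, forceGrid = forceGrid, turns = nT,
      g4Available = g4Available, config = cfg, params = prm)
}

#' Simulate an ensemble of force ramps
#'
#' Each ramp's G4 availability is an independent Bernoulli draw with
#' probability `pFold(cfg) * availabilityFactor(nT)`; the realised flags are
#' recorded as ground truth (attribute `g4Available`) for classifier
#' validation. The master `seed` deterministically spawns one sub-stream per
#' ramp.
#'
#' @inheritParams simulateRamp
#' @param nRamps Number of ramps, `>= 1`.
#' @param g4Available Optional logical vector to force the availability
#'   flags instead of drawing them.
#' @return List of [ForceRamp] with attribute `g4Available` (logical vector).
#' @export
simulateEnsemble <- function(nRamps, nT, cfg = TetherConfig(),
                             prm = SimParams(),
                             forceGrid = defaultForceGrid(), seed = NULL,
                             g4Available = NULL) {
  stopifnot(nRamps >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- cfg@pFold * availabilityFactor(nT)
  flags <- if (is.null(g4Available)) stats::runif(nRamps) < p
           else rep_len(as.logical(g4Available), nRamps)
  rampSeeds <- sample.int(.Machine$integer.max - 1L, nRamps)
  ramps <- lapply(seq_len(nRamps), function(i)
    simulateRamp(nT, cfg, prm, flags[i], forceGrid, seed = rampSeeds[i]))
  attr(ramps, "g4Available") <- flags
  ramps
}

#' Simulate an ensemble and return variance profiles only
#'
#' Memory-light companion of [simulateEnsemble()] for large ensembles: each
#' ramp is simulated, reduced to its [VarianceProfile] (per-force variance
#' over the analysis window plus per-force mean extension) and discarded.
#' Ramp-level RNG streams are spawned exactly as in [simulateEnsemble()].
#'
#' @inheritParams simulateEnsemble
#' @param window Variance analysis window in s.
#' @return List with elements `profiles` (list of [VarianceProfile]),
#'   `g4Available` (ground-truth flags) and `pAvailable` (the Bernoulli
#'   probability used).
#' @export
simulateEnsembleProfiles <- function(nRamps, nT, cfg = TetherConfig(),
                                     prm = SimParams(), window = 4,
                                     forceGrid = defaultForceGrid(),
                                     seed = NULL, g4Available = NULL) {
  stopifnot(nRamps >= 1)
  if (any(diff(forceGrid) <= 0)) stop("force grid must be strictly increasing")
  if (window > prm@dwell) stop("window must not exceed the trace dwell")
  if (!is.null(seed)) set.seed(seed)
  p <- cfg@pFold * availabilityFactor(nT)
  flags <- if (is.null(g4Available)) stats::runif(nRamps) < p
           else rep_len(as.logical(g4Available), nRamps)
  rampSeeds <- sample.int(.Machine$integer.max - 1L, nRamps)
  nW <- as.integer(round(window * prm@sampleRate))
  profiles <- vector("list", nRamps)
  for (r in seq_len(nRamps)) {
    set.seed(rampSeeds[r])
    occ <- stateOccupancies(forceGrid, nT, cfg, prm, flags[r])
    le <- .stateExtensions(forceGrid, nT, cfg, prm)
    v <- numeric(length(forceGrid))
    m <- numeric(length(forceGrid))
    for (i in seq_along(forceGrid)) {
      ext <- .simulateExtensionRow(le[i, ], occ[i, ], prm)
      v[i] <- stats::var(ext[seq_len(nW)])
      m[i] <- mean(ext)
    }
    profiles[[r]] <- new("VarianceProfile", force = forceGrid, variance = v,
                         meanExtension = m, window = window, turns = nT,
                         meta = list(g4Available = flags[r],
                                     construct = cfg@construct,
                                     ion = cfg@ion, seed = rampSeeds[r]))
  }
  list(profiles = profiles, g4Available = flags, pAvailable = p)
}
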