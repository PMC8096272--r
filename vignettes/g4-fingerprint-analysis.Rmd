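---
title: "Detecting G-quadruplex folding in supercoiled DNA from extension fluctuations"
author: "g4twist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting G-quadruplex folding in supercoiled DNA from extension fluctuations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4twist)
```

## The measurement this package models

In a magnetic-tweezers (MT) experiment a double-stranded DNA tether is held
between a surface and a superparamagnetic bead; translating and rotating the
magnets sets the pulling force $F$ and the number of imposed turns $n_t$, and
the bead height reports the end-to-end extension $L_e(t)$. Under negative
supercoiling the torsional stress can be stored in two ways: as plectonemes,
which shorten the tether, or as denaturation bubbles, which do not. At low
force plectonemes win; above a characteristic force $F_C$ bubbles win. At the
coexistence force the molecule hops between the two arrangements and the
variance of the extension, $\sigma^2_{L_e}$, measured as a function of force,
shows a bell-shaped peak whose maximum defines $F_C$.

When the tether carries a G-quadruplex (G4) forming promoter region, a second,
lower-force route opens: a partial denaturation bubble just large enough to
expose the G-rich region lets the G4s fold, absorbing part of the imposed
twist. On such ramps the variance profile shows **two** peaks — a G4
sub-transition at $F_{C1}$ and the main plectoneme/bubble transition at
$F_{C2}$ — and this double peak is the nanomechanical fingerprint of G4
folding. The fraction of double-peaked ramps tracks the G4-stabilising quality
of the buffer cation (K$^+$ > Na$^+$ > Li$^+$) and collapses when the G4
motifs are mutated away.

The package implements the full analysis chain — variance profiling, peak
classification, characteristic-force statistics, worm-like-chain (WLC) and
logistic steepness fits, and the energy bookkeeping — together with a
synthetic trace generator that reproduces the study conditions, so every stage
is testable without instrument data (none are publicly deposited).

## The synthetic generator

### Three-state occupancy model

No microscopic model of the trace dynamics is available at the level of
detail the analysis needs, so the generator is deliberately phenomenological:
a three-state model with sequential logistic occupancies,

* **P** — plectonemic: $L_e^P = \max(0,\, L_e^D - s\,|n_t|)$, with $s$ the
  plectoneme slope (nm per turn);
* **G** — G4 intermediate: $L_e^G = L_e^P + s\, n_{G4}$, where
  $n_{G4} = 72/10.4 \approx 6.9$ turns are relaxed when the 72 bp promoter
  region opens as one event (single- and double-G4 substructures are not
  resolved by the measurement and are not modelled);
* **D** — denaturation bubble: $L_e^D$ is the Marko–Siggia WLC extension at
  the applied force.

With the G4 pathway available the occupancies follow two sequential logistics
centred at $F_{C1} = 0.37$ pN and $F_{C2} = 0.69$ pN (the ensemble means of
the double-peak cohort); without it, a single logistic centred at $F_{C2}$.
For $n_t \ge 0$ duplex opening does not occur and the model stays in P — no
ramp at positive supercoiling can ever show a double peak, matching the
positive-torsion control.

The noiseless-limit variance profile is the closed-form mixing variance
$\sum_i p_i (L_e^i)^2 - (\sum_i p_i L_e^i)^2$, exposed as `mixingVariance()`
and used as the generator's ground truth throughout the tests.

### Calibrated defaults, and why two of them are not free

* **Transition width 0.035 pN.** The width sets both the variance-peak width
  (FWHM $\approx 3.5 w \approx 0.12$ pN, matching published profiles) and the
  depth of the dip between the two peaks. This parameter cannot be made much
  wider: because the D state is ~1.6 µm long, a width of 0.08 pN would leak
  enough D occupancy into the region between $F_{C1}$ and $F_{C2}$ to fill
  the dip completely and merge the two peaks into one — the double-peak
  fingerprint would vanish from the generator's own ground truth.
* **Plectoneme slope 75 nm/turn.** The slope is not reported by the
  experiment and enters the generator only through the extension released
  per relaxed turn. It is calibrated so that the programmed work gain of the
  G4 pathway — the area between the noiseless G4-available and G4-free mean
  curves, $\approx s\, n_{G4} (F_{C2}-F_{C1})$ — equals the measured
  24 kcal/mol work difference. Both parameters remain configurable in
  `SimParams()`.
* **Hopping kinetics.** Telegraph hopping between adjacent occupied states
  uses detailed-balance rates with a base pair rate of 20 s$^{-1}$, i.e. a
  correlation time of ~50 ms at a transition midpoint. This is required by
  the observed convergence of the variance with acquisition window: the
  expected windowed variance is $V(1 - 2\tau/T_w)$ to first order, so
  reaching $\ge 95\%$ of the asymptote by $T_w \approx 3$ s — the behaviour
  that justifies the $\ge 4$ s acquisition rule — needs $\tau \lesssim 80$
  ms. Slower kinetics (say $\tau = 0.5$ s) would reach only ~67% by 3 s.
* **Noise.** Bead Brownian motion is an additive Ornstein–Uhlenbeck process
  (SD 15 nm, 50 ms relaxation); tracking noise is white with SD 10 nm, the
  axial resolution of the instrument. The long-window trace variance is then
  mixing variance + $15^2 + 10^2$ nm$^2$, an identity the tests verify
  against long simulations.
* **Availability probabilities.** Each ramp draws a Bernoulli flag for
  whether the G4 pathway is available, with calibrated probabilities
  (wt: 0.35/0.18/0.11 in KCl/NaCl/LiCl; mut: 0.12). The residual 12% in the
  mutant reflects non-G4 relaxations (hairpin/cruciform-like events); these
  are not ion-coordination dependent, so the mutant probability is taken
  ion-independent. The dependence on $n_t$ is phenomenological
  (`availabilityFactor()`): a bubble-opening factor growing with $|n_t|$
  times a plectoneme-occlusion factor decaying beyond ~30 turns, normalised
  to 1 at the reference $n_t = -40$. It produces an interior maximum near
  $n_t = -30$ and <3% at $n_t = -100$; this is generator behaviour, not an
  inference from data.

### What the generator does not emulate

Fixed transition centres (no molecule-to-molecule scatter of $F_{C}$), no
camera/image formation, no torque readout, no drift, no multi-G4
substructure, and a single global transition width. Passing tests therefore
demonstrate that the *analysis* recovers what the generator programs under
realistic noise and kinetics — not that the generator is a complete physical
model of the instrument.

## Analysis operations and numerical choices

**Variance profiles.** Per force, the unbiased sample variance over the
first 4 s of the trace (the acquisition rule; configurable). The profile
object also carries per-force mean extensions, from which cohort mean curves
are built.

**Peak classification.** The published analysis never states an operational
double-peak rule, so the package fixes one and exposes every threshold:
Gaussian smoothing (SD 0.03 pN on the 0.01 pN grid), topographic prominence
of local maxima, a prominence threshold of 0.10 of the global maximum, a
minimum separation of 0.10 pN, and a baseline guard (the global maximum must
exceed 3 times the lower-quartile baseline, otherwise the profile is flat at
the noise floor and no peak is called — this is what keeps
positive-supercoiling ramps at zero double peaks). The prominence fraction
deserves a note: the G4 sub-peak's mixing variance is
$(s\,n_{G4})^2/4 \approx 6.7\times10^4$ nm$^2$ against a main peak of
$\approx 3.1\times10^5$ nm$^2$, i.e. ~20% of the global maximum, so a
threshold of 0.25 would *by construction* never call a double peak; 0.10
sits safely between the programmed sub-peak and the profile noise. Halving
the smoothing changes the ensemble double-peak rate by under 5 percentage
points (tested). Ties in prominence break by height, then by lower force;
characteristic forces are read at the smoothed-profile maxima without
sub-grid interpolation (the 0.01 pN grid is finer than any tolerance of
interest).

**WLC fits.** Marko–Siggia interpolation, fitted in the extension-versus-
force direction with `minpack.lm`, weights $1/\mathrm{sd}^2$ when SDs are
available (a documented switch disables weighting), starts at
$L_0 = 1.05 \times$ max extension and $L_p = 50$ nm, bounds
$L_0 \in (0, 2\times$max$]$, $L_p \in [1, 200]$ nm. The numeric inverse of
the force law solves the equivalent cubic by safeguarded Newton iteration to
relative residuals below $10^{-12}$.

**Logistic steepness.** The printed transition model
$L_e = a + b/(1+e^{(F-F_1)/S_0})$ is fitted exactly as printed; since the
data increase with force, the fitted $b$ is negative (the sign is reported,
not flipped) and $S_0 > 0$ is enforced. Parameters are bounded to the
observed force window and amplitude scale because the unbounded model has a
degenerate exponential-tail solution that occasionally captures noisy
curves; three starting points are tried ($S_0$ = 0.5, 0.1, and 0.05 at the
steepest data point). Non-convergence is reported explicitly, never replaced
by defaults.

**S0 mixture.** One- and two-component Gaussian mixtures of the
untransformed $S_0$ samples, fitted by EM (mclust, unequal variances; the
one-component fit is the closed-form MLE), components ordered by mean,
relative areas = weights, model choice by BIC with both fits always
reported. Distributions are compared by the two-sided Wilcoxon rank-sum test
(normal approximation with tie correction).

**Energetics.** The cost per relaxed turn $\alpha = \pi\sqrt{8 B F_C}$ with
$B = L_p k_B T$; the transition-energy ratio $\sqrt{F_{C1}/F_{C2}} = 0.73$,
identical to the $\alpha$ ratio since $B$ cancels (tested to machine
precision); the ledger $120 \to 88$ kcal/mol with a net gain of 32 kcal/mol,
consistent with three G4s at ~10 kcal/mol each; and the work difference as
the area $\int \Delta L_e\, dF$ between cohort mean curves, which equals the
work difference $\int F\, dL_e$ when the curves coincide at the range ends
(a warning is raised otherwise), converted at 1 pN nm = 0.14393 kcal/mol.
$k_B T$ is pinned at 4.11 pN nm (298 K). Display rounding is two significant
figures; machine outputs keep full precision.

**Supercoiling density.** $\sigma = n_t/(N_b/10.4)$ as printed. Note a
printed value of $\sigma = -0.070$ at $n_t = -40$ corresponds to
$N_b \approx 5943$, not the construct's 6680 bp (which gives $-0.062$);
$5943$ bp is close to the fitted contour length divided by 0.34 nm/bp. The
function implements the formula; both base-pair choices appear in the tests
and neither is silently preferred.

## Synthetic-average curves

Published mean force-extension curves are averages over hundreds of
individual ramps, with error bars showing the *ensemble* SD. The synthetic
counterparts (`syntheticWLCCurve()`, `syntheticLogisticCurve()`) therefore
carry heteroscedastic ensemble SDs in their error-bar column while the
curve itself fluctuates at the corresponding standard error
(SD$/\sqrt{n}$ with $n = 100$ curves for the logistic case). WLC curves use
the thermal fluctuation scale $\sqrt{k_B T\, dL_e/dF}$ plus tracking noise
for their SDs.

## Problem sizes used in the tests and acceptance script

Chosen as the smallest ensembles that leave the statistics comfortably
inside their tolerances: 200 WLC replicate curves, 100 logistic replicates,
400-ramp ensembles for the double-peak rate, 200 + 200 ramps for
characteristic-force recovery, 10,000 mixture samples, and 30 + 30 ramps per
cohort for the work area. A full ramp is 296 forces × 5 s × 300 Hz.

## Known limitations

* The generator's fixed transition centres make characteristic-force
  distributions narrower than measured ones (measured SDs ~0.11–0.15 pN
  reflect molecule-to-molecule variability the generator omits); ensemble
  *means* are the comparable quantities.
* The double-peak thresholds are one defensible operationalisation of a
  judgement the original analysis left unstated; all four knobs are exposed
  and versioned with the package.
* The energy ledger takes the 120 kcal/mol duplex opening cost of the
  G4-forming region as a cited constant; no sequence-based melting
  prediction is attempted.
* A worked end-to-end run is in `runPipeline()`; per-ramp failures are
  logged and skipped rather than aborting the ensemble.
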