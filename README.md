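# g4twist

Fluctuation-fingerprint analysis of G-quadruplex (G4) folding inside
negatively supercoiled double-stranded DNA, as measured by magnetic
tweezers.

## The problem

G4-forming sequences in gene promoters sit inside the duplex, so a G4 can
only fold after the two strands separate locally. Under negative
supercoiling a DNA tether relieves torsional stress either by writhing into
plectonemes (which shorten it) or by opening denaturation bubbles (which do
not); the two arrangements coexist at a characteristic force `F_C`, where
the extension fluctuates strongly. A G4-forming region adds a second,
cheaper opening route: a partial bubble exposes the G-rich tract, the G4s
fold and absorb part of the imposed twist, and a *second* peak appears in
the extension-variance-versus-force profile at a lower force `F_C1 < F_C2`.
That double peak is a single-molecule fingerprint of G4 folding, and the
two characteristic forces quantify the free-energy discount the G4s grant
to duplex opening:

- energy per relaxed turn: `alpha = pi * sqrt(8 * B * F_C)`, with bending
  constant `B = Lp * kB * T`;
- transition-energy ratio: `sqrt(F_C1 / F_C2) = sqrt(0.37/0.69) = 0.73`;
- applied to a ~120 kcal/mol duplex opening cost this gives ~88 kcal/mol
  along the G4-assisted path — a net gain of ~32 kcal/mol, consistent with
  three G4s at ~10 kcal/mol each, and with the ~24 kcal/mol work-area
  difference between double-peak and single-peak mean force-extension
  curves.

The package is aimed at single-molecule biophysicists who want to run this
analysis on force-ramp trace data (plain TSV in, plain TSV/JSON out) or to
study its statistical behaviour on the bundled, calibrated trace generator.

## What's inside

- `simulateTrace()` / `simulateRamp()` / `simulateEnsemble()` /
  `simulateEnsembleProfiles()` — three-state (plectoneme / G4 intermediate /
  bubble) trace generator with telegraph hopping, bead and tracking noise;
- `varianceProfile()`, `detectCharacteristicForces()`,
  `classifyEnsemble()` — the variance fingerprint and single/double-peak
  classification;
- `wlcForce()`, `wlcExtension()`, `fitWLC()` — Marko-Siggia worm-like-chain
  model and fitting of contour/persistence length at zero twist;
- `fitLogistic()`, `fitS0Mixture()`, `compareS0Distributions()` — logistic
  steepness statistic `S0` and its Gaussian-mixture / rank-sum analysis;
- `alphaPerTurn()`, `energyRatio()`, `g4Ledger()`, `energyLedger()`,
  `workArea()`, `supercoilDensity()` — the energy bookkeeping;
- `readTrace()` / `writeRamp()` / `runPipeline()` — text formats and the
  simulate-analyze-report orchestrator (plus a thin CLI in
  `inst/scripts/g4twist.R`).

See the vignette in `vignettes/g4-fingerprint-analysis.Rmd` for the model,
calibrations and numerical choices.

## Worked example

```r
library(g4twist)

# 60 wild-type ramps in 150 mM KCl at nt = -40 (G4 pathway available on a
# ~35% Bernoulli draw per ramp), reduced to variance profiles
ens <- simulateEnsembleProfiles(60, -40, TetherConfig("wt", "KCl"),
                                SimParams(), seed = 42)
classifyEnsemble(ens$profiles)
#> EnsembleSummary: n = 60 ramps
#>   double 15 (25.0% +- 5.6), single 45, none 0
#>   fC_single  mean 0.691 pN, sd 0.005 pN (n = 45)
#>   fC1_double mean 0.371 pN, sd 0.005 pN (n = 15)
#>   fC2_double mean 0.691 pN, sd 0.005 pN (n = 15)

energyLedger()
#> G4 energy ledger
#>   F_C1 = 0.37 pN, F_C2 = 0.69 pN, B = 189.1 pN nm^2
#>   alpha(F_C1) = 74 pN nm/turn (11 kcal/mol/turn)
#>   alpha(F_C2) = 100 pN nm/turn (15 kcal/mol/turn)
#>   transition-energy ratio sqrt(F_C1/F_C2) = 0.73
#>   duplex opening cost   120 kcal/mol
#>   G4-assisted path cost 88 kcal/mol
#>   net gain              32 kcal/mol
#>   expected 3 x 10 kcal/mol per G4 = 30 kcal/mol
```

15 of 60 ramps (25 ± 5.6%) show the double-peak fingerprint — within
sampling error of the 35% availability at this ensemble size — with the G4
sub-transition at 0.371 ± 0.005 pN and the main transition at
0.691 ± 0.005 pN; the single-peak ramps peak at the same upper force. The
ledger then turns the two forces into the energy discount summarised above.

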