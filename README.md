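# nfkbswitch

Digital NF-κB activation under dose- and duration-modulated inflammatory
stimulation: a mechanistic single-cell ODE model with extrinsic
population noise, stimulation screens, and a trajectory-analysis pipeline
for single-cell nuclear-translocation data.

## The problem

Cells sense bacterial LPS (via TLR4/Myddosome/TRAF6) and host-derived TNF
(via TNFR) through the IKK–IκBα–NF-κB module, and respond *digitally*: a
cell either translocates essentially all of its NF-κB to the nucleus or
does not respond at all. Population-level dose-responses therefore report
the **fraction of cells that switch**. Two questions organize the
package:

1. **What controls the fraction of activating cells?** The stimulus
   integral, or *area* `A = concentration × duration` (ng·s/ml). A cell
   with receptor scale `R` activates iff `R·A` exceeds its critical
   value; lognormal receptor noise then gives the population activation
   curve as a lognormal CDF in area — the *Area Rule*:
   `f(A) = Φ((ln A − ln A₅₀)/σ)`, independent of how the area is
   delivered (brief strong pulse, long weak pulse, square-wave train).
2. **What controls response timing and heterogeneity?** The temporal
   profile. Duration-modulated strong inputs move the fraction across its
   whole range with fast, uniform timing; concentration-modulated
   sustained inputs move the same fraction but introduce long,
   heterogeneous delays at low dose. Short-strong (SS) and long-low (LL)
   inputs of equal area activate equal fractions yet are distinguishable
   by response delay.

The per-cell model couples a slow receptor integrator, autocatalytic
(nucleation-growth) TRAF6/Myddosome assembly, cooperative IKK activation
with Hill kinetics (`T⁴/(K⁴+T⁴)` for LPS; the TNF variant is
non-cooperative), and the classical IκBα and A20 negative feedbacks, with
exact conservation of total NF-κB. Sealed microfluidic chambers deplete
ligand through cellular internalization; perfused chambers hold it
constant.

## Worked example

Three inputs: two equal-area deliveries (500 ng/ml × 10 s and
50 ng/ml × 100 s, both 5000 ng·s/ml) and a weak sustained stimulation.

```r
library(nfkbswitch)
params <- lpsModel()                          # calibrated LPS defaults
cells  <- samplePopulation(populationConfig(n_cells = 100, seed = 1))
eq     <- equilibratePopulation(params, cells)

short <- simulateCondition(params, cells, makePulse(500, 10),  equilibria = eq)
long  <- simulateCondition(params, cells, makePulse(50, 100),  equilibria = eq)
low   <- simulateCondition(params, cells, makeSustained(0.5),  equilibria = eq)
screenSummary(list(short, long, low))
```

```
  dose_ng_ml duration_s area_ng_s_ml fraction_active median_peak_time_min cv_peak_time
1      500.0         10         5000            0.59                 34.0   0.03972777
2       50.0        100         5000            0.58                 35.0   0.03304135
3        0.5      21600        10800            0.12                 89.5   0.31587601
```

The two equal-area pulses activate the same fraction (59% vs 58%, well
within binomial error) with identical fast timing (median first peak 34–35
min, CV ≈ 0.04): the Area Rule in action. The weak sustained input
activates only the high-receptor tail of the population (12%), and those
responders are slow (median 89.5 min) and heterogeneous (CV ≈ 0.32):
dose modulation trades activation probability against timing uniformity.

Other entry points: `runScreen()` (dose × duration grids, tidy summary),
`collapseScore()` (Area-Rule collapse diagnostic), `minimalDuration()`,
`squareWaveEquivalence()`, `areaResponseModel()`/`analyticFraction()`
(integrate-and-threshold reduction), `trajectoryFeatures()` /
`summarizeCondition()` / `fitHill()` / `pairwiseTests()` /
`ssLlDiscriminator()` (analysis pipeline, which also reads imaging-style
trajectory CSVs via `readTrajectories()`), `generateDataset()` (synthetic
microscopy tracks with ground truth), and the command-line tool
`inst/scripts/nfkbtool.R` with subcommands `simulate`, `analyze`,
`areascan`, `squarewave`, `calibrate`, `synth`.

The calibrated default parameter files ship in `inst/extdata/` and were
produced by the committed script `inst/scripts/calibrate_defaults.R`; the
methods vignette (`vignettes/nfkbswitch-methods.Rmd`) describes the model,
the calibration anchors and the numerical choices.

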