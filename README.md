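# PulseTWED

Elastic kernel classification of arterial pulse waveforms.

In quantitative pulse diagnosis, a single-period pressure waveform from the
radial artery is assigned to one of five classical morphology patterns —
*moderate*, *slippery*, *taut*, *hollow*, *unsmooth*. The hard part is that
the patterns vary strongly within a class and homologous landmarks
(percussion, tidal and dicrotic waves) shift in time from beat to beat, so
rigid pointwise distances confuse timing with shape. PulseTWED is for
researchers in biomedical signal processing who want a complete, testable
implementation of the elastic-kernel approach to this problem: every stage
from the raw 150 Hz record to the cross-validated error table, plus a
seeded synthetic generator that stands in for clinical data.

## What is inside

* **Elastic metrics.** The time warp edit distance
  (`twedDistance`) — an edit distance whose delete/match costs carry
  time-stamp penalties weighted by a stiffness pair (λ, ν) —
  implemented as an iterative dynamic program (C++), with a memoized
  reference recursion (`twedBruteforce`) kept as an independent oracle.
  Also ERP (`erpDistance`, gap element 0) and the Euclidean baseline.
  TWED and ERP satisfy the metric axioms, including the triangle
  inequality; the test suite checks this on thousands of random triples.
* **Elastic Gaussian kernels.** `gtwedKernel`/`gerpKernel` compute
  `k(A, B) = exp(−d(A, B)² / 2σ²)`; `gramMatrix` builds Gram matrices with
  distance-matrix caching so σ and C sweeps never re-run the dynamic
  programs. Metricity is necessary but not sufficient for positive
  definiteness, so `psdDiagnostics` reports the Gram spectrum and
  `repairGram` offers spectrum clipping / diagonal loading; by default
  training uses the Gram as-is.
* **Kernel SVM.** An SMO solver for the box-constrained dual on
  precomputed (possibly indefinite) Gram matrices, with one-vs-one
  multiclass voting (`trainPulseSVM`, `predict`) and 1-nearest-neighbour
  baselines (`nnClassify`).
* **Preprocessing.** Daubechies-4 MODWT denoising and baseline-drift
  removal, derivative-based onset (foot) detection, median-template period
  selection, and piecewise-linear length normalization to 150 samples
  (`preprocessPipeline` and its stages).
* **Synthetic data.** A seeded generator of labelled periods and raw noisy
  drifting multi-period records with exact ground truth
  (`generateDataset`, `generateRecord`), class proportions 80/55/80/16/16.
* **Evaluation.** Stratified 10-fold nested cross-validation with an inner
  tuning split and grid search over (λ, ν, σ, C) (`nestedCV`,
  `gridSearch`), confusion-matrix and average-error-rate (AER) reporting
  (`aerFromConfusion`, `renderCVReport`).

A thin command-line front end (`inst/scripts/pulsetwed`) exposes
`simulate`, `preprocess`, `dist`, `gram`, `train` and `evaluate`.

## Worked example

```r
library(PulseTWED)

# a labelled synthetic dataset of normalized 150-sample periods
ds <- generateDataset(c(moderate = 30, slippery = 20, taut = 30,
                        hollow = 8, unsmooth = 8), seed = 42)

# GTWED-SVM at the operating point lambda = 0.01, nu = 0.25, sigma = 100, C = 100
kp <- kernelParams(sigma = 100, metric = "twed",
                   elastic = elasticParams(lam = 0.01, nu = 0.25))
model <- trainPulseSVM(ds, kp, C = 100)

probe <- generateDataset(c(moderate = 5, hollow = 5), seed = 99)
table(predicted = predict(model, probe), actual = pulseLabels(probe))
#>           actual
#> predicted  moderate slippery taut hollow unsmooth
#>   moderate        4        0    0      0        0
#>   slippery        0        0    0      1        0
#>   taut            1        0    0      0        0
#>   hollow          0        0    0      4        0
#>   unsmooth        0        0    0      0        0

# raw record in, normalized period out
g <- generateRecord("slippery", nPeriods = 8, seed = 7)
period <- preprocessPipeline(g$record)
cor(period@values, g$template)
#> [1] 0.9622196
```

Eight of the ten held-out periods are classified correctly (one moderate
is taken for taut, one hollow for slippery — exactly the confusions the
morphology overlap predicts), and the preprocessing chain recovers a
period correlating at r = 0.96 with the clean generating template despite
25 dB noise, powerline interference and 30% baseline drift.

The published worked example reproduces as well: feeding the printed
confusion matrix of the GTWED-SVM on the 2470-waveform clinical dataset
into `aerFromConfusion` (class totals 800/550/800/160/160) returns a total
AER of 9.43% and per-class AERs of 10.12 / 15.27 / 3.12 / 15.00 / 11.88
percent.

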