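---
title: "Elastic kernel classification of pulse waveforms: models, parameters, design"
author: "PulseTWED"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic kernel classification of pulse waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PulseTWED)
```

## The problem

Pulse diagnosis assigns an arterial pressure waveform to one of a small set
of morphology patterns — here the five classical categories *moderate*,
*slippery*, *taut*, *hollow* and *unsmooth*. Automatic classification is
hard for two reasons: the patterns show strong intraclass variation (an
atypical moderate waveform with a faint tidal wave looks much like a
slippery one), and physiological timing varies from beat to beat, so
homologous landmarks (percussion, tidal, dicrotic waves) drift in position.
A rigid pointwise distance confounds those time shifts with genuine shape
differences. This package classifies single-period waveforms with a support
vector machine whose kernel is built from an *elastic metric* — a
time-series distance that tolerates local time shifts while still
satisfying the triangle inequality.

## Distances and kernels

**Time warp edit distance (TWED).** For series $A_1^m$ and $B_1^n$ with
time stamps, TWED is the cost of the cheapest sequence of edit operations,
computed by an $(m{+}1)\times(n{+}1)$ dynamic program. Deleting sample
$a_i$ costs $d(a_i, a_{i-1}) + \nu\,(t_{a_i}-t_{a_{i-1}}) + \lambda$;
matching $(a_i, b_j)$ costs
$d(a_i,b_j) + d(a_{i-1},b_{j-1}) + \nu(|t_{a_i}-t_{b_j}| +
|t_{a_{i-1}}-t_{b_{j-1}}|)$; deletion in $B$ is symmetric. Two parameters
set the *stiffness*: $\lambda \ge 0$ (signal units) is a flat penalty per
deletion, $\nu \ge 0$ (signal units per time unit) prices time-stamp
mismatch. At $\nu \to \infty$ TWED approaches a rigid alignment; at
$\nu = 0$ it warps freely. TWED satisfies all metric axioms, which the test
suite verifies empirically on thousands of random triples.

Both series are padded with a virtual sample of value 0 at time 0; cell
$(0,0)$ is 0 and the first row/column accumulate repeated deletions from
that padded start. The recursion as usually printed leaves the $a_0/b_0$
terms undefined; this boundary is the standard completion. Timestamps
default to 1-based sample indices, so $\nu$ is "per sample" for normalized
periods. Samples here are scalar, so every $L_p$ norm of a sample
difference reduces to the absolute difference and the exposed `p`
parameter is inert (it is kept for multivariate extension).

**ERP.** The edit distance with real penalty compares unmatched samples
against a constant gap element (0 by default); it is the other elastic
*metric* used as a baseline, with the classical three-way dynamic program.

**Euclidean distance** on equal-length series is the rigid baseline.

**Gaussian elastic kernels.** The GTWED kernel is
$k(A,B) = \exp(-d_{\mathrm{twed}}^2(A,B) / 2\sigma^2)$, and GERP is the
analogue with ERP. Gaussian kernels built on a *non*-metric (such as
dynamic time warping) are provably indefinite; metricity is necessary but
not sufficient, so the package reports the Gram spectrum
(`psdDiagnostics`) and never assumes positive definiteness. On the default
synthetic dataset the GTWED Gram at the operating point has a small
negative minimum eigenvalue (about $-0.17$ for $n = 247$); training
proceeds on the Gram as-is by default, with `repairGram` offering spectrum
clipping ("clip": zero negative eigenvalues, reconstitute, re-normalize the
diagonal) and diagonal loading ("jitter") as conservative alternatives.

## The SVM

The binary classifier solves the usual soft-margin dual
$\max_\alpha \sum_i \alpha_i - \tfrac12 \sum_{ij} \alpha_i\alpha_j y_iy_j
k(x_i,x_j)$ subject to $0 \le \alpha_i \le C$, $\sum_i \alpha_i y_i = 0$,
with a precomputed Gram matrix. The solver is an SMO working-set method
(maximal violating pair) run to a KKT gap of $10^{-3}$ by default; on an
indefinite Gram the pair curvature is floored at $10^{-12}$, so the solver
either reaches a stationary point or fails loudly with a pointer to the
spectrum diagnostics. The bias is the mean of $y_i - f_{\setminus b}(x_i)$
over free support vectors ($0 < \alpha_i < C$), falling back to the
midpoint of the KKT bounds when every support vector is at the box; samples
with $\alpha_i \le 10^{-8}$ are pruned from the stored model. Multiclass
classification is one-vs-one over the $K(K-1)/2$ class pairs with majority
voting; vote ties go to the class with the larger summed absolute decision
value, then to the fixed class order. The solver's optimality is tested
against brute-force maximization on small problems, and the two-point
problem with $k_{12} = 0.5$ reproduces its closed form
($\alpha = 1/(1-k_{12}) = 2$, $b = 0$).

## Preprocessing raw records

The chain from a raw pressure record (150 Hz) to one normalized 150-sample
period is: wavelet denoising, wavelet baseline removal, onset detection,
period selection, length normalization. All wavelet steps use a
maximal-overlap (undecimated) discrete wavelet transform with the
Daubechies-4 filter and reflection boundary; the MODWT reconstructs
exactly, needs no power-of-two length, and avoids the shift dependence of
the decimated transform.

* **Denoising** soft-thresholds the detail coefficients with a per-level
  universal threshold whose noise scale is the median absolute deviation
  of the level-1 details divided by 0.6745 (level-$j$ MODWT noise shrinks
  by $2^{(j-1)/2}$ relative to level 1). The default depth is **2 levels**:
  at 150 Hz those bands ($\approx$ 18.75–75 Hz) carry measurement noise and
  50 Hz powerline but essentially no waveform morphology, while
  thresholding levels 3–4 ($\approx$ 4.7–18.75 Hz) visibly erodes the
  systolic upstroke. Two levels still halve the RMS error of a 20 dB SNR
  record in the package's tests.
* **Baseline removal** zeroes the level-**7** approximation and
  reconstructs, removing $\approx$ [0, 0.59] Hz. The cut sits above the
  respiration/drift band (0.2–0.4 Hz; residual gain 0.03–0.12) and below
  cardiac fundamentals (0.9–1.7 Hz for 0.6–1.1 s periods; gain
  $\ge 0.94$). A one-octave-lower cut (level 8, [0, 0.29] Hz) leaves a
  0.2 Hz drift at 14% RMS and most of a 0.4 Hz drift in place; one octave
  higher would bite into slow heart rates. The residual distortion on a
  drift-free pulse train is below 10% of signal RMS (edge effects
  included), the price of removing the entire drift band with an
  octave-band filter.
* **Onset detection** finds one systolic upstroke per period as local
  maxima of the smoothed first difference: candidates are selected
  greedily, strongest first, under a refractory separation of
  `minPeriodS` (0.35 s, i.e. at most 171 bpm), and then thresholded at
  half the 75th percentile of the surviving candidates' heights.
  Computing that percentile over *all* derivative maxima would let
  micro-wiggles dominate it, which is why the refractory pass comes
  first. Each onset (the foot) is found by walking back from the upstroke
  while the smoothed upslope exceeds 5% of the upstroke's peak slope —
  a percentage-of-peak-slope rule that skips the rise but is not fooled
  by shallow noise shoulders in the diastolic floor.
* **Period selection**: every complete onset-to-onset segment is
  provisionally resampled to 150 points; the segment closest in Euclidean
  distance to the pointwise median of the provisional set is returned raw.
  The median template makes the choice robust to a single corrupted beat;
  ties go to the earliest segment.
* **Length normalization** resamples the chosen segment to exactly 150
  points by piecewise-linear interpolation (the 1-D reading of "bilinear"
  resampling; endpoints are preserved exactly). Amplitude normalization
  (min-range scaling to [0, 1]) is available but **off** by default:
  waveform force is itself diagnostic, so amplitude is preserved unless
  the user opts out.

## The synthetic generator

No public dataset of labelled single-period pulse waveforms exists at this
scale, so the package ships a seeded generator that emulates the structure
of such a collection: five classes in proportions 80/55/80/16/16 (a
tenth-scale version of the 800/550/800/160/160 composition the method was
originally evaluated on), strong intraclass variation, local time shifts,
and — at the record level — baseline drift, powerline interference and
white noise.

Each class template is a sum of Gaussian components on normalized period
time (percussion, tidal and dicrotic waves, plus a broad low *diastolic
runoff* that keeps the waveform decaying into the next foot — without it
the tail would be identically zero and the foot ill-defined). Taut pulses
have three equally weighted variants (plateau, high tidal, double hump);
unsmooth pulses are low-amplitude and broad with a 2% amplitude-modulated
high-frequency ripple. One period is produced by jittering component
amplitudes ($\pm 20\%$), centers ($\pm 0.02$) and widths ($\pm 20\%$) —
cohort-level diversity, calibrated so that a 1NN classifier with TWED
stays above 85% leave-one-out accuracy while the rigid Euclidean baseline
errs visibly more — followed by a smooth monotone time warp
$w(u) = u + \sum_{k=1}^3 \epsilon_k \sin(\pi k u)$ with
$\epsilon_k \sim N(0, 0.005^2)$ redrawn until $w' > 0$.

Records concatenate several beats of one "subject": the template variant is
fixed, per-beat jitter is much smaller (5%/0.008/8%), durations are drawn
once per record from 0.6–1.1 s and jittered 5% per beat. Disturbances are
additive: sinusoidal drift (0.2–0.4 Hz at 30% of peak-to-peak), 50 Hz
powerline (2%), and white noise at a declared SNR (25 dB default,
realized within $\pm$1 dB). The generator returns exact onset positions
and the clean class template as ground truth.

What the generator does *not* emulate: genuine hemodynamics (no Windkessel
model), sensor contact-pressure effects, arrhythmia, motion artifacts
beyond an optional injected spike, or the label noise of expert
adjudication. Passing the package's tests therefore shows that the method
chain is implemented correctly and behaves as designed under controlled
morphology, not that clinical error rates are reproduced. One consequence
is worth stating plainly: on Gaussian-bump morphology with small warps,
1NN-ERP is as good as — at some seeds better than — 1NN-TWED, so the small
TWED-over-ERP advantage reported on clinical data is not consistently
reproduced here, while the kernel SVM's advantage over plain 1NN and the
elastic metrics' advantage over the Euclidean baseline are.

## Evaluation protocol

`nestedCV` implements 10-fold cross-validation with an inner tuning split:
the outer folds are **stratified** (with only 16 samples in the rare
classes, unstratified folds can lose a class entirely; `stratify = FALSE`
restores plain random splitting). Within each training set, 1/9 is split
off (stratified, seeded) for tuning; every grid point is fitted on the
remaining 8/9 and scored on that tuning part; the winner — ties broken in
grid iteration order, $\lambda$ outermost, then $\nu$, $\sigma$, $C$ — is
refitted on the full training set and scored on the held-out fold. Default
grids: $\lambda \in 10^{-5..0}$, $\nu \in \{0, 0.25, 0.5, 0.75, 1\}$,
$\sigma \in 10^{-2..4}$, $C \in 10^{-3..5}$.

Distance matrices are cached per (metric, $\lambda$, $\nu$) over the full
dataset and shared across folds, methods and the $(\sigma, C)$ sweep — the
dynamic programs dominate runtime, and the $(\sigma, C)$ sweep reuses each
matrix dozens of times. Error rates are reported as per-class and total
average error rates (AER) from the pooled confusion matrix; percentages
print with two decimals, round-half-even. `aerFromConfusion` accepts
explicit class totals so that published confusion tables whose rows are
internally inconsistent with the stated class sizes can still be rendered
as printed.

Problem sizes used throughout the documentation and tests: 247-period
datasets, 50-record preprocessing batches of 8 beats, and a reduced tuning
grid ($\lambda = 10^{-2}$, full $\nu$, $\sigma \in \{10, 10^2, 10^3\}$,
$C \in \{1, 10^2, 10^4\}$) for the method comparison — sizes at which a
complete nested comparison runs in about a minute on one core.

## Numerical choices, in one place

* TWED/ERP dynamic programs in C++; pure-R memoized recursions are kept as
  independent oracles (`twedBruteforce`, and the test suite's naive ERP).
* Three-way minima break ties in the order delete-A, match, delete-B; only
  the distance value is returned, so tie order is unobservable.
* Kernel evaluation underflows to exactly 0 for $d^2/2\sigma^2 \gtrsim
  745$; choose $\sigma$ on the scale of the distances (the tuning grid
  does this automatically).
* Eigenvalue tolerance for "numerically PSD" is $-10^{-8}$ on
  unit-diagonal matrices; spectrum clipping targets $\ge -10^{-10}$.
* SMO: KKT tolerance $10^{-3}$ (training) with bound-membership tolerance
  $10^{-12} C$; support-vector pruning at $\alpha > 10^{-8}$, with the
  pruning skipped if it would break $\sum \alpha_i y_i = 0$ beyond
  $10^{-6}$.
* All text formats use '.' decimals, comma/tab delimiters and `%.17g`
  number formatting, so write→read→write cycles are byte-identical; model
  JSON uses 17 significant digits for exact double round trips.
* Every stochastic routine takes a seed and restores the caller's RNG
  state, so a `CVReport` is a pure function of (data, method, grid, k,
  seed).

## Known limitations

* Validation is synthetic-only; absolute error rates on clinical data are
  out of reach by construction, and the generator's difficulty is set by
  its jitter configuration, not estimated from data.
* GTWED's positive definiteness is neither guaranteed nor assumed; on
  indefinite Grams the SMO solution is a stationary point, not a certified
  global optimum. The default mirrors common practice (train on the Gram
  as-is); `repairGram` is available when convexity matters more than
  fidelity to the raw kernel.
* The preprocessing chain assumes a single-channel record with at least
  two beats and a roughly stationary heart rate; it has no arrhythmia
  handling.
* `p` (the $L_p$ order) is exposed but inert for scalar series.
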