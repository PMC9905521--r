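---
title: "chaosbench: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chaosbench: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

Whether an empirical time series was produced by a chaotic system is a
recurring question for biomedical signals — gait, eye movement,
photoplethysmography — where sensitivity to initial conditions carries
physiological meaning (for locomotion it underlies local dynamic
stability, quantified elsewhere through the largest Lyapunov exponent).
Classical nonlinear indicators (correlation dimension, Lyapunov-exponent
estimates from delay embeddings) are fragile under noise, which motivates
supervised learning: train a classifier on signals whose dynamical class
is known *by construction*, then apply it to empirical data.

`chaosbench` builds that training material. It generates labelled time
series from fifteen dynamical systems of dimension 1–3 — five chaotic
dissipative flows (the Ueda, Lorenz, Rössler, Halvorsen and Rucklidge
systems), five periodic linear oscillators, three explicitly defined
quasi-periodic signals, and two non-periodic damped linear systems — and
reproduces the benchmark's validation study: three chaos-vs-non-chaos
classification experiments with a small LSTM and a small one-dimensional
CNN.

## Generation model

Each ODE system is integrated over `[0, T_max]` with the adaptive
Dormand–Prince Runge–Kutta 4(5) pair (`deSolve::ode(method = "ode45")`),
then resampled at `s = 1000` equidistant times. Each quasi-periodic
signal is evaluated in closed form on the same grid. A full build runs
`v = 1000` randomized simulations per model; since the systems together
have 33 state variables and every state variable is treated as one
univariate signal, the full dataset holds 33,000 series in 15,000 CSV
files.

**Augmentation.** Run `r` of a model replaces each element of the
canonical initial vector `x0` by `x0[i] * (2*rand() - 1)` with
independent uniform draws, so randomized elements stay inside
`(-|x0[i]|, |x0[i]|)` and zero elements remain zero. For the
quasi-periodic models the scalar `x0 = 2π` is a phase offset; the same
rule applies to it, giving phases uniform on `(-2π, 2π)`. This follows
from reading the augmentation rule as element-wise and universal; it is
the only interpretation that treats all fifteen models identically.

**Grid convention.** The sampling grid is `t_i = i·T_max/(s-1)`,
`i = 0…s-1`, inclusive of both endpoints. The source material states
only that values are interpolated at equidistant points covering 0 to
`T_max`; the inclusive grid is the simplest convention consistent with
that statement, and it is recorded here rather than inferred from the
deposited files.

**Resampling.** By default the solver's continuous extension (dense
output) supplies the grid values. Cubic-spline and linear resampling of
a four-fold oversampled solution are available through
`generatorConfig(interpolation =)`; on the smooth linear systems the
dense and cubic routes agree to about `1e-4`, which bounds the
interpolation sensitivity of the dataset.

**Tolerances.** `relTol = 1e-3`, `absTol = 1e-6` — the classical
defaults of adaptive RK45 implementations, exposed in the configuration.
The test suite checks the integrator against closed-form and
matrix-exponential solutions of the seven linear systems (max error
well below `1e-3`) and against energy conservation of the undamped
oscillators.

**Seeds.** One master seed spawns a per-(model, run) child seed by a
fixed integer recurrence (`childSeed()`); each run seeds R's RNG with
its child seed before drawing its initial condition. Two builds with the
same master seed are therefore byte-identical, and any single run can be
regenerated in isolation from the manifest. A run whose integration
produces non-finite values redraws its initial condition from the same
stream, up to 10 retries; with the printed canonical conditions all
fifteen systems are bounded and no retry is expected, but the contract
exists and retries are recorded in the manifest.

**File format.** One CSV per run: 1,000 rows, one column per state
variable, no header, no time column, LF line ends. Numbers are written
with the shortest decimal representation that parses back to the exact
double (15–17 significant digits), so files are diff-stable across
platforms and `readRun(writeRun(x))` is exact. Per-model archives are
store-only zip files. Byte equality with the originally deposited
archives is *not* a goal — the original RNG state is unpublished — only
format and counts match.

## Phase portraits

For univariate signals the package reconstructs a pseudo-state space
with axes (signal, first derivative, second derivative), the
Takens-style embedding used for the quasi-periodic portraits (which wind
on a torus). The derivative approximations are second-order central
differences on interior points; the exact stencil used for the original
figures is not published, so the standard scheme was chosen and is
documented here. A length-1000 signal yields 998 portrait points.

## Validation experiments

Experiments use seven of the fifteen systems: chaotic `CHA_1`, `CHA_2`,
`CHA_3` against non-chaotic `OSC_1`, `DOSC_2`, `IOSC`, `DS_1` — 8
chaotic and 9 non-chaotic signal dimensions, hence 17,000 signals at the
full scale. Signals are cut into contiguous non-overlapping segments of
`Y ∈ {50, 100, 200}` samples; experiment 1 uses all segments,
experiment 2 only the first segment of each signal, and experiment 3
re-evaluates the experiment-1/-2 classifiers on a test set augmented
with all quasi-periodic segments (labelled non-chaos, since
quasi-periodicity is not chaos — but resembles it, which is the point of
the experiment).

Three design choices deserve explanation:

* **Counterbalancing.** The published set sizes (17,000 training
  signals; 12,652 test signals) are consistent with *no* down-sampling:
  the 8-vs-9 dimension split is nearly balanced by construction. The
  package therefore treats class balancing as an optional switch
  (seeded, down-sampling the majority class at the whole-signal level so
  segments of one signal never straddle sets) rather than a default.
* **Hold-out test batch.** The derivation of the published 12,652-signal
  test pool is not stated and its experiment-3 counterparts are
  internally inconsistent (313,100 ≠ 253,040 + 60,000), so the package
  generates an independent hold-out batch with fresh seeds instead of
  carving the training runs; its size defaults to 0.744 of the training
  runs, the published test/train ratio.
* **Split.** The training pool is split 75 % / 25 % into train and
  validation at the run level, stratified by class and seeded; all state
  variables and all segments of a run share the run's assignment, so no
  information leaks between sets.

## Classifiers

No deep-learning framework is part of the package's dependency set; the
two architectures are implemented directly (RcppArmadillo kernels,
finite-difference-checked gradients):

* **LSTM** — input `(batch, Y, 1)` → LSTM with 4 units → dropout 0.5 →
  dense layer with 2 sigmoid units. 106 trainable parameters for the
  published configuration.
* **CNN** — Conv1D → ReLU → batch normalization → dropout 0.5, then
  flatten → dense(2, sigmoid). Filter count and kernel width are not
  stated in the original account (figures only); the package defaults to
  32 filters of width 3. The "extended" CNN used for the first-segment
  experiment stacks three such blocks with 32/64/64 filters
  (`arch = "cnn_deep"`).

Training follows the published recipe where stated: categorical
cross-entropy, Adam with learning rate 0.001, batch size 64. The
epoch budget is unstated; the default is 30 epochs with early stopping
on validation loss (patience 5, best weights restored). The original
description pairs a *sigmoid* output layer with *categorical*
cross-entropy; the package follows that literally — the two sigmoid
scores are normalized to probabilities inside the loss (exactly what
TensorFlow's categorical cross-entropy does with non-logit inputs),
clipped at `1e-7` before normalization so fully saturated outputs stay
finite — and exposes a conventional softmax head behind
`outputActivation = "softmax"` for comparison. Batch-norm uses the
common ε = 0.001 and momentum 0.99. Dropout masks and shuffling draw
from R's RNG, so training is bit-reproducible under `trainSeed` (the
kernels are single-threaded).

Chaos is always the positive class of the confusion matrix, and
accuracy is the headline metric, as in the original tables
(`publishedResults()` reproduces those tables; recomputing accuracy from
their counts matches the printed values to within 0.001 — several rows
are truncated rather than rounded).

## Desk-scale study conditions

The package's own validation (test suite and `scripts/acceptance.R`)
runs the experiments at 100 runs per model — one tenth of the full
benchmark, about 25,000 training segments at `Y = 50` — which keeps a
full scaled replication within minutes on one CPU while leaving the
accuracy picture intact (experiment-1 accuracies land between 0.95 and
0.99 against ≥ 0.95 reported originally, and the experiment-3
quasi-periodic degradation reproduces in most cells — strongly for the
LSTM and for the CNN at Y = 100). One caveat of the reduced scale: the
CNN at Y = 200 can classify quasi-periodic windows *better* than its
base test set (its base accuracy sits around 0.965 rather than the
full-scale 0.985), so for that cell the augmented test set does not
always lower accuracy. Full-size runs (1,000 runs per model) are
supported through the same functions and the CLI
(`reproduce-all --runs 1000`).

## What the generator does and does not emulate

The synthetic signals are noise-free, stationary in their generating
mechanism, and perfectly labelled; empirical biomedical series are none
of these. Passing the package's checks demonstrates that the generation
pipeline and classifiers reproduce the benchmark's *in-distribution*
behaviour — it says nothing about robustness to measurement noise
(noise injection is deliberately out of scope), non-stationarity, or
dynamics outside the fifteen systems. Chaotic hyperjerk systems
(dimension > 3) are likewise out of scope.

## Known limitations

* Exact reproduction of the deposited CSV bytes is impossible (original
  RNG state unknown) and not attempted.
* The published test-pool sizes (12,652 / 15,652 / 15,655) are
  underivable from the stated procedure; the package's hold-out
  proportions approximate them instead.
* The LSTM/CNN results are stochastic; scaled-down point comparisons use
  a ±0.03 band over three training seeds, and the reproduction script
  measures, per cell, the best-validation model of three training seeds
  (the 4-unit LSTM under dropout 0.5 occasionally converges poorly on a
  single unlucky seed).
* At desk scale the first-segment experiment trains on 1,700 segments
  (a tenth of the original), so its accuracies sit a few points below
  the published full-scale values.
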