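# chaosbench

Synthetic, perfectly labelled time series for learning to recognize
chaotic dynamics — and the benchmark experiments that validate them.

## The problem

Deciding whether an observed signal was generated by a chaotic system is
a long-standing question for biomedical time series (gait, eye movement,
photoplethysmography), where classical indicators such as
Lyapunov-exponent estimates are notoriously noise-sensitive. A
supervised alternative needs training data whose dynamical class is known
*by construction*. `chaosbench` generates exactly that: **33,000 time
series from 15 dynamical systems** of dimension 1–3 —

| class | systems |
|---|---|
| chaotic | Ueda (`CHA_1`), Lorenz (`CHA_2`), Rössler (`CHA_3`), Halvorsen (`CHA_4`), Rucklidge (`CHA_5`) |
| periodic | linear oscillators `OSC_1`, `OSC_2`, `DOSC_1`, `DOSC_2`, `IOSC` |
| quasi-periodic | `QPS_1`–`QPS_3`, sums of two sinusoids with irrational frequency ratio (π, golden ratio, e) |
| non-periodic | damped linear systems `DS_1`, `DS_2` |

Each ODE system is integrated with an adaptive Dormand–Prince
Runge–Kutta 4(5) scheme over `[0, T_max]` and resampled at `s = 1000`
equidistant points; quasi-periodic signals are evaluated in closed form.
Data augmentation draws `v = 1000` initial conditions per model by
scaling each element of the canonical initial vector `x0` with an
independent uniform(−1, 1) factor — `x = x0 ∘ (2·rand() − 1)`. Every
state variable is one univariate signal, so Σ dim_j · v = 33·1000 =
33,000 series in 15,000 header-less CSV files (one column per state
variable), with a JSON manifest of per-run seeds that makes any build
byte-reproducible.

The package also implements the benchmark's validation study: segmenting
the signals into windows of Y ∈ {50, 100, 200} samples and training two
small classifiers — an LSTM (4 units → dropout 0.5 → 2-unit sigmoid
dense layer; 106 parameters) and a 1-D CNN (Conv1D → ReLU → batch norm →
dropout → flatten → dense) — with Adam (learning rate 0.001, batch 64)
on categorical cross-entropy, chaos being the positive class. Experiment
1 uses all segments, experiment 2 only each signal's first segment, and
experiment 3 re-tests the trained models on a test set augmented with
quasi-periodic segments, whose chaos-like character degrades accuracy.
No deep-learning framework is required: both networks are implemented in
the package (RcppArmadillo), with gradient correctness checked against
finite differences in the test suite.

## Worked example

```r
library(chaosbench)

## three augmented Lorenz runs, reproducibly seeded
man <- generateDataset("CHA_2", generatorConfig(runsPerModel = 3, masterSeed = 7))
man
#> GenerationManifest: 1 models x 3 runs (3 files, 9 univariate series), seed 7
man@runs[, c("model", "run", "seed", "retries")]
#>   model run    seed retries
#> 1 CHA_2   1 2483490       0
#> 2 CHA_2   2 2483491       0
#> 3 CHA_2   3 2483492       0
round(head(trajectoryValues(man@trajectories[[1]]), 3), 4)
#>         [,1]      [,2]     [,3]
#> [1,] -0.4557 -161.5030  -8.2620
#> [2,]  6.1178  125.6321  82.9121
#> [3,] -6.3914  -76.4260 102.3331
```

The first row is the randomized initial condition (inside
(−10,10)×(−200,200)×(−10,10) for the Lorenz `x0 = [10, 200, 10]`); run
seeds are derived deterministically from the master seed, so the same
call reproduces the same files byte for byte.

`publishedResults()` carries the benchmark's reported confusion tables;
the package's `ConfusionCounts` arithmetic reproduces the printed
accuracies:

```r
row <- subset(publishedResults(), experiment == 1 & arch == "lstm" & segment == 50)
new("ConfusionCounts", tp = row$tp, fn = row$fn, tn = row$tn, fp = row$fp)
#> ConfusionCounts (chaos positive): TP 107389  FN 5651  TN 139992  FP 8  | accuracy 0.978
```

A scaled experiment end to end (100 runs/model, ~3 min on one CPU):

```r
sig <- experimentSignals(runsPerModel = 100, masterSeed = 1)
res <- runExperiment(1, "lstm", Y = 100, sig, seed = 1)
res$accuracy        # about 0.98 against >= 0.95 reported at full scale
```

## Command line

```sh
Rscript inst/cli/chaosbench.R generate --models all --runs 1000 --seed 1 --out data/
Rscript inst/cli/chaosbench.R package --dir data/
Rscript inst/cli/chaosbench.R portrait --file data/QPS_1/QPS_1_0001.csv --out qps1.png
Rscript inst/cli/chaosbench.R reproduce-all --runs 100 --seed 1 --out reports/
```

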