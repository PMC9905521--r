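## Shared fixtures, built once per test run and cached in the session.

.fixtureEnv <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (is.null(.fixtureEnv[[key]]))
    assign(key, expr, envir = .fixtureEnv)
  .fixtureEnv[[key]]
}

## small generation batches for functional tests
smallSignals <- function() {
  fixture("sig_small", experimentSignals(runsPerModel = 10,
                                         testRunsPerModel = 8,
                                         masterSeed = 3, includeQPS = TRUE))
}

## the desk-scale study conditions (100 runs/model) used by the
## classification checks
scaledSignals <- function() {
  fixture("sig_scaled", experimentSignals(runsPerModel = 100,
                                          masterSeed = 1, includeQPS = TRUE))
}

## trained experiment-1 classifiers, keyed by (arch, Y, seed)
exp1Result <- function(arch, Y, seed = 1L) {
  fixture(sprintf("e1_%s_%d_%d", arch, Y, seed),
          runExperiment(1, arch, Y, scaledSignals(), seed = seed))
}

exp2Result <- function(arch, Y, seed = 1L) {
  fixture(sprintf("e2_%s_%d_%d", arch, Y, seed),
          runExperiment(2, arch, Y, scaledSignals(), seed = seed))
}
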