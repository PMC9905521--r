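## S4 classes shared across the package. Validity methods enforce the
## structural contracts; accessors live next to the modules that use them.

setClassUnion("integerOrNA", c("integer", "logical"))

#' ModelSpec: one dynamical system
#'
#' A `ModelSpec` describes a single benchmark system: its symbol (e.g.
#' `"CHA_2"` for the Lorenz attractor), behaviour class, state dimension,
#' parameter values, canonical initial condition `x0`, the final value
#' `tMax` of the independent variable, and whether the model is given as a
#' system of ODEs (`form = "ode"`) or as an explicit signal formula
#' (`form = "explicit"`, the quasi-periodic models, whose scalar `x0` is a
#' phase offset).
#'
#' @slot symbol model identifier.
#' @slot name human-readable name.
#' @slot behaviourClass one of `"chaotic"`, `"periodic"`, `"quasi-periodic"`,
#'   `"non-periodic"`.
#' @slot dim integer state dimension (1, 2 or 3).
#' @slot params named numeric parameter vector.
#' @slot x0 canonical initial condition (length `dim`).
#' @slot tMax end of the integration / evaluation interval.
#' @slot form `"ode"` or `"explicit"`.
#' @slot equations the state equations (or signal formula) as text, so the
#'   registry is self-documenting.
#' @seealso [modelRegistry()]
#' @export
setClass("ModelSpec",
  representation(
    symbol = "character",
    name = "character",
    behaviourClass = "character",
    dim = "integer",
    params = "numeric",
    x0 = "numeric",
    tMax = "numeric",
    form = "character",
    equations = "character"
  )
)

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (!object@behaviourClass %in%
      c("chaotic", "periodic", "quasi-periodic", "non-periodic"))
    msg <- c(msg, "unknown behaviourClass")
  if (!object@form %in% c("ode", "explicit"))
    msg <- c(msg, "form must be 'ode' or 'explicit'")
  if (!object@dim %in% 1:3)
    msg <- c(msg, "dim must be 1, 2 or 3")
  if (length(object@x0) != object@dim)
    msg <- c(msg, "length(x0) must equal dim")
  if (!is.finite(object@tMax) || object@tMax <= 0)
    msg <- c(msg, "tMax must be positive")
  if ((object@dim == 1L) != (object@form == "explicit"))
    msg <- c(msg, "dim 1 if and only if form 'explicit'")
  if (length(msg)) msg else TRUE
})

#' GeneratorConfig: dataset generation settings
#'
#' Holds the generation constants of the benchmark: `runsPerModel` (v, number
#' of randomized initial conditions per model; 1,000 for the full dataset),
#' `samples` (s, time-series length; 1,000), the master seed, the integrator
#' tolerances, the resampling interpolation mode, and the retry budget for
#' diverging runs.
#'
#' @slot runsPerModel integer, runs (files) per model.
#' @slot samples integer, samples per run.
#' @slot masterSeed integer master seed; per-run child seeds are derived from
#'   it (see [childSeed()]).
#' @slot relTol,absTol adaptive RK45 tolerances.
#' @slot interpolation `"dense"` (the solver's continuous extension, default),
#'   `"cubic"` or `"linear"` (spline / linear resampling of an oversampled
#'   solution).
#' @slot retryBudget maximum redraws of the initial condition when a run
#'   diverges.
#' @export
setClass("GeneratorConfig",
  representation(
    runsPerModel = "integer",
    samples = "integer",
    masterSeed = "integer",
    relTol = "numeric",
    absTol = "numeric",
    interpolation = "character",
    retryBudget = "integer"
  )
)

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  if (object@runsPerModel < 1L) msg <- c(msg, "runsPerModel must be >= 1")
  if (object@samples < 2L) msg <- c(msg, "samples must be >= 2")
  if (object@relTol <= 0 || object@absTol <= 0)
    msg <- c(msg, "tolerances must be positive")
  if (!object@interpolation %in% c("dense", "cubic", "linear"))
    msg <- c(msg, "interpolation must be dense, cubic or linear")
  if (object@retryBudget < 0L) msg <- c(msg, "retryBudget must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Trajectory: one simulated run
#'
#' Equidistant times spanning `[0, tMax]` plus the `samples x dim` matrix of
#' state values, with provenance (model symbol, run index, child seed, the
#' randomized initial condition actually used).
#'
#' @slot modelSymbol,runIndex,seed provenance.
#' @slot ic the (possibly randomized) initial condition; for explicit models
#'   the scalar phase.
#' @slot times equidistant sampling times, `times[1] = 0`,
#'   `times[s] = tMax`.
#' @slot values `s x dim` numeric matrix, one column per state variable.
#' @export
setClass("Trajectory",
  representation(
    modelSymbol = "character",
    runIndex = "integer",
    seed = "integer",
    ic = "numeric",
    times = "numeric",
    values = "matrix"
  )
)

setValidity("Trajectory", function(object) {
  msg <- character()
  s <- length(object@times)
  if (s < 2L) msg <- c(msg, "need at least two samples")
  if (nrow(object@values) != s)
    msg <- c(msg, "nrow(values) must equal length(times)")
  if (!all(is.finite(object@values))) msg <- c(msg, "non-finite values")
  dt <- diff(object@times)
  if (any(dt <= 0)) msg <- c(msg, "times must be strictly increasing")
  if (s > 2L && (max(dt) - min(dt)) > 1e-8 * max(dt))
    msg <- c(msg, "times must be equidistant")
  if (length(msg)) msg else TRUE
})

#' GenerationManifest: bookkeeping of a dataset build
#'
#' Records, for every generated run, the model symbol, run index, derived
#' child seed, initial condition, retry count, and (when written to disk) the
#' output file, together with the configuration that produced it. With the
#' same master seed and configuration the build is reproducible byte for
#' byte.
#'
#' @slot runs data.frame with one row per run (columns `model`, `run`,
#'   `seed`, `retries`, `file`) and the initial condition in the
#'   list-column `ic`.
#' @slot models character vector of generated model symbols.
#' @slot config the [GeneratorConfig-class] used.
#' @slot dir output directory, `NA` for in-memory builds.
#' @slot trajectories list of [Trajectory-class] objects when the build kept
#'   them in memory (empty for dry runs or disk-only builds).
#' @export
setClass("GenerationManifest",
  representation(
    runs = "data.frame",
    models = "character",
    config = "GeneratorConfig",
    dir = "character",
    trajectories = "list"
  )
)

#' RunFile: one CSV file of the published layout
#'
#' @slot path file path.
#' @slot modelSymbol,runIndex provenance parsed from the file name.
#' @slot values `s x dim` matrix read from / written to the file.
#' @export
setClass("RunFile",
  representation(
    path = "character",
    modelSymbol = "character",
    runIndex = "integer",
    values = "matrix"
  )
)

#' EmbeddedPortrait: derivative-based phase-space embedding
#'
#' Pseudo-state-space reconstruction of a univariate signal with axes
#' (signal, first-derivative approximation, second-derivative approximation),
#' computed with central differences on interior points.
#'
#' @slot points `(n-2) x 3` matrix, columns `x`, `dx`, `d2x`.
#' @slot dt sampling interval.
#' @export
setClass("EmbeddedPortrait",
  representation(points = "matrix", dt = "numeric")
)

setValidity("EmbeddedPortrait", function(object) {
  msg <- character()
  if (ncol(object@points) != 3L) msg <- c(msg, "points must have 3 columns")
  if (!all(is.finite(object@points))) msg <- c(msg, "non-finite points")
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (length(msg)) msg else TRUE
})

#' SegmentConfig: windowing settings for the experiments
#'
#' @slot length segment length Y (50, 100 or 200 in the benchmark).
#' @slot mode `"all_segments"` (split the whole series into contiguous
#'   non-overlapping windows) or `"first_segment_only"`.
#' @export
setClass("SegmentConfig",
  representation(length = "integer", mode = "character")
)

setValidity("SegmentConfig", function(object) {
  msg <- character()
  if (object@length < 1L) msg <- c(msg, "segment length must be >= 1")
  if (!object@mode %in% c("all_segments", "first_segment_only"))
    msg <- c(msg, "mode must be all_segments or first_segment_only")
  if (length(msg)) msg else TRUE
})

#' SignalSet: univariate signals with provenance
#'
#' Each state variable of a multidimensional run is one univariate signal.
#' `info` has one row per signal (`model`, `run`, `var`, `class`, `label`);
#' `signals` holds the numeric vectors in the same order.
#'
#' @export
setClass("SignalSet",
  representation(info = "data.frame", signals = "list")
)

setValidity("SignalSet", function(object) {
  if (nrow(object@info) != length(object@signals))
    "info rows and signals must match" else TRUE
})

#' LabelledSegmentSet: classification units of the experiments
#'
#' Fixed-length windows with binary chaos labels (chaos is the positive
#' class) and source bookkeeping back to (model, run, variable, segment).
#'
#' @slot values `n x Y` matrix, one segment per row.
#' @slot label factor with levels `non_chaos`, `chaos`.
#' @slot source data.frame with columns `model`, `run`, `var`, `segment`.
#' @export
setClass("LabelledSegmentSet",
  representation(values = "matrix", label = "factor", source = "data.frame")
)

setValidity("LabelledSegmentSet", function(object) {
  msg <- character()
  if (nrow(object@values) != length(object@label))
    msg <- c(msg, "one label per segment required")
  if (!identical(levels(object@label), c("non_chaos", "chaos")))
    msg <- c(msg, "label levels must be non_chaos, chaos")
  if (nrow(object@source) != nrow(object@values))
    msg <- c(msg, "one source row per segment required")
  if (length(msg)) msg else TRUE
})

#' ExperimentSplit: train / validation / test sets of one experiment
#'
#' @slot expId experiment number (1, 2 or 3).
#' @slot segmentConfig the [SegmentConfig-class] used.
#' @slot train,validation,test [LabelledSegmentSet-class] objects.
#' @export
setClass("ExperimentSplit",
  representation(
    expId = "integer",
    segmentConfig = "SegmentConfig",
    train = "LabelledSegmentSet",
    validation = "LabelledSegmentSet",
    test = "LabelledSegmentSet"
  )
)

#' ConfusionCounts: binary confusion matrix with chaos positive
#'
#' @slot tp,fn,tn,fp counts; chaotic-class segments are the positive class.
#' @export
setClass("ConfusionCounts",
  representation(tp = "numeric", fn = "numeric", tn = "numeric", fp = "numeric")
)

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fn, object@tn, object@fp)
  if (any(v < 0) || any(v != floor(v))) "counts must be non-negative integers"
  else TRUE
})

#' ClassifierConfig: architecture and training hyperparameters
#'
#' Defaults follow the published setup where stated (LSTM with 4 units,
#' dropout 0.5, categorical cross-entropy, Adam with learning rate 0.001,
#' batch size 64) and documented package choices where the original account
#' is silent (30 epochs with early stopping patience 5; 32 filters of width
#' 3 for the single-block CNN; 3 blocks with 32/64/64 filters for the deep
#' CNN).
#'
#' @slot arch `"lstm"`, `"cnn"` or `"cnn_deep"`.
#' @slot segmentLength input sequence length Y.
#' @slot lstmUnits LSTM units (default 4).
#' @slot dropoutRate dropout rate in `[0, 1)` (default 0.5).
#' @slot convFilters integer vector, filters per convolution block.
#' @slot convKernel kernel width (default 3).
#' @slot learningRate Adam learning rate (default 0.001).
#' @slot batchSize minibatch size (default 64).
#' @slot epochs maximum training epochs (default 30).
#' @slot patience early-stopping patience on validation loss, `NA` to
#'   disable (default 5).
#' @slot outputActivation `"sigmoid"` (as printed in the original
#'   description) or `"softmax"`.
#' @slot trainSeed RNG seed for initialization, shuffling and dropout.
#' @export
setClass("ClassifierConfig",
  representation(
    arch = "character",
    segmentLength = "integer",
    lstmUnits = "integer",
    dropoutRate = "numeric",
    convFilters = "integer",
    convKernel = "integer",
    learningRate = "numeric",
    batchSize = "integer",
    epochs = "integer",
    patience = "integerOrNA",
    outputActivation = "character",
    trainSeed = "integer"
  )
)

setValidity("ClassifierConfig", function(object) {
  msg <- character()
  if (!object@arch %in% c("lstm", "cnn", "cnn_deep"))
    msg <- c(msg, "arch must be lstm, cnn or cnn_deep")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must be in [0, 1)")
  if (object@segmentLength < object@convKernel && object@arch != "lstm")
    msg <- c(msg, "segment shorter than convolution kernel")
  if (!object@outputActivation %in% c("sigmoid", "softmax"))
    msg <- c(msg, "outputActivation must be sigmoid or softmax")
  if (object@arch == "cnn" && length(object@convFilters) != 1L)
    msg <- c(msg, "cnn uses exactly one convolution block")
  if (object@arch == "cnn_deep" && length(object@convFilters) < 2L)
    msg <- c(msg, "cnn_deep needs at least two convolution blocks")
  if (length(msg)) msg else TRUE
})

#' Classifier: an (un)trained LSTM or CNN
#'
#' @slot config the [ClassifierConfig-class].
#' @slot params named list of weight arrays.
#' @slot trained logical.
#' @slot history per-epoch training history (loss/accuracy on train and
#'   validation), empty until trained.
#' @export
setClass("Classifier",
  representation(
    config = "ClassifierConfig",
    params = "list",
    trained = "logical",
    history = "data.frame"
  )
)
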