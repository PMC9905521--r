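## Trajectory generation: randomized initial conditions, adaptive
## Dormand-Prince RK45 integration (deSolve, method "ode45") with equidistant
## resampling, closed-form evaluation of the explicit quasi-periodic models,
## and the full dataset build.

#' Construct a GeneratorConfig
#'
#' @param runsPerModel number of randomized runs (files) per model; the full
#'   benchmark uses 1,000.
#' @param samples time-series length; the benchmark uses 1,000.
#' @param masterSeed master seed from which per-run child seeds are derived.
#' @param relTol,absTol adaptive RK45 tolerances (the classical defaults
#'   1e-3 / 1e-6 of adaptive RK45 implementations).
#' @param interpolation `"dense"` (solver continuous extension, default),
#'   `"cubic"` or `"linear"`.
#' @param retryBudget maximum initial-condition redraws per diverging run.
#' @return a [GeneratorConfig-class].
#' @export
generatorConfig <- function(runsPerModel = 1000L, samples = 1000L,
                            masterSeed = 1L, relTol = 1e-3, absTol = 1e-6,
                            interpolation = c("dense", "cubic", "linear"),
                            retryBudget = 10L) {
  new("GeneratorConfig",
    runsPerModel = as.integer(runsPerModel), samples = as.integer(samples),
    masterSeed = as.integer(masterSeed), relTol = relTol, absTol = absTol,
    interpolation = match.arg(interpolation),
    retryBudget = as.integer(retryBudget))
}

#' Deterministic child-seed derivation
#'
#' One master seed spawns an independent child seed for every (model, run)
#' pair so that single runs are regenerable in isolation:
#' `child = (master * 69069 + modelIndex * 1000003 + run) mod (2^31 - 1)`,
#' evaluated exactly in double precision. `modelIndex` is the position of the
#' model in [modelRegistry()].
#'
#' @param masterSeed integer master seed.
#' @param modelIndex 1-based model index in the registry.
#' @param run 1-based run index.
#' @return integer child seed in `[0, 2^31 - 2]`.
#' @export
childSeed <- function(masterSeed, modelIndex, run) {
  m <- 2147483647
  as.integer((((as.numeric(masterSeed) %% m) * 69069) %% m +
              as.numeric(modelIndex) * 1000003 + as.numeric(run)) %% m)
}

#' Randomize an initial condition
#'
#' Augmentation rule of the benchmark: each element of the canonical initial
#' vector is multiplied by an independent `2*rand() - 1` factor, i.e. by a
#' uniform draw on (-1, 1). Elements equal to zero therefore stay zero, and
#' every randomized element lies strictly inside `(-|x0_i|, |x0_i|)`.
#' Draws consume the current R RNG stream, which the caller owns (seed it
#' with the run's child seed for reproducibility).
#'
#' @param x0 canonical initial vector (scalar phase for explicit models).
#' @return randomized vector of the same length.
#' @export
randomizeIC <- function(x0) {
  x0 * (2 * runif(length(x0)) - 1)
}

.sampleTimes <- function(tMax, s) seq(0, tMax, length.out = s)

## Per-model derivative closures with parameter values baked in: the
## integrator calls the right-hand side thousands of times per run, so the
## generic modelRHS() dispatch is hoisted out of the inner loop. A test
## asserts agreement with modelRHS() for every ODE model.
.desolveRHS <- function(model) {
  p <- model@params
  switch(model@symbol,
    CHA_1 = {
      b <- p[["b"]]; A <- p[["A"]]; Om <- p[["Omega"]]
      function(t, x, parms)
        list(c(x[2], -x[1]^3 - b * x[2] + A * sin(Om * t)))
    },
    CHA_2 = {
      sg <- p[["sigma"]]; bt <- p[["beta"]]; rh <- p[["rho"]]
      function(t, x, parms)
        list(c(-sg * x[1] + sg * x[2],
               rh * x[1] - x[2] - x[1] * x[3],
               -bt * x[3] + x[1] * x[2]))
    },
    CHA_3 = {
      a <- p[["a"]]; b <- p[["b"]]; cc <- p[["c"]]
      function(t, x, parms)
        list(c(-x[2] - x[3], x[1] + a * x[2], b + x[3] * (x[1] - cc)))
    },
    CHA_4 = {
      a <- p[["a"]]
      function(t, x, parms)
        list(c(-a * x[1] - 4 * x[2] - 4 * x[3] - x[2]^2,
               -4 * x[1] - a * x[2] - 4 * x[3] - x[3]^2,
               -4 * x[1] - 4 * x[2] - a * x[3] - x[1]^2))
    },
    CHA_5 = {
      k <- p[["k"]]; la <- p[["lambda"]]
      function(t, x, parms)
        list(c(-k * x[1] + la * x[2] - x[2] * x[3], x[1], -x[3] + x[2]^2))
    },
    OSC_1 = ,
    OSC_2 = {
      a <- p[["a"]]; b <- p[["b"]]
      function(t, x, parms) list(c(a * x[2], b * x[1]))
    },
    DOSC_1 = function(t, x, parms)
      list(c(x[2], -0.2 * x[1] - 0.08 * x[2] + 0.01)),
    DOSC_2 = function(t, x, parms)
      list(c(x[2], -0.04 * x[1] - 0.016 * x[2] + 0.01)),
    IOSC = function(t, x, parms)
      list(c(x[2], -0.2 * x[1] + 0.08 * x[2] + 0.01)),
    DS_1 = function(t, x, parms)
      list(c(-0.01 * x[1] + 0.01 * x[2],
             -0.001 * x[1] - 0.01 * x[2],
             0.05 * x[1] - 0.03 * x[3])),
    DS_2 = function(t, x, parms)
      list(c(-0.05 * x[1] + 0.01 * x[2],
             -0.001 * x[1] - 0.01 * x[2],
             0.05 * x[1] - 0.08 * x[3])),
    function(t, x, parms) list(modelRHS(model, t, x))
  )
}

#' Integrate an ODE model on the equidistant benchmark grid
#'
#' Solves the model's state equations over `[0, tMax]` with the adaptive
#' Dormand-Prince Runge-Kutta 4(5) pair (deSolve method `"ode45"`), then
#' resamples at `samples` equidistant times `t_i = i * tMax / (s - 1)`,
#' `i = 0..s-1`. With `interpolation = "dense"` the solver's continuous
#' extension delivers the grid values directly; `"cubic"`/`"linear"`
#' integrate on a four-fold oversampled grid and interpolate down. The
#' result is deterministic given (model, ic, config).
#'
#' @param model a [ModelSpec-class] with `form == "ode"`.
#' @param ic initial condition of length `model@dim`.
#' @param config a [GeneratorConfig-class].
#' @param runIndex,seed provenance carried into the [Trajectory-class].
#' @return a [Trajectory-class].
#' @export
integrateModel <- function(model, ic, config = generatorConfig(),
                           runIndex = 1L, seed = NA_integer_) {
  stopifnot(is(model, "ModelSpec"), is(config, "GeneratorConfig"))
  if (model@form != "ode")
    stop("integrateModel() needs an ODE-form model", call. = FALSE)
  if (length(ic) != model@dim)
    stop("initial condition has wrong length", call. = FALSE)
  s <- config@samples
  grid <- .sampleTimes(model@tMax, s)
  rhs <- .desolveRHS(model)
  solveAt <- function(times) {
    out <- try(deSolve::ode(
      y = as.numeric(ic), times = times, func = rhs, parms = NULL,
      method = "ode45", rtol = config@relTol, atol = config@absTol),
      silent = TRUE)
    if (inherits(out, "try-error") || nrow(out) < length(times) ||
        !all(is.finite(out)))
      stop("integration diverged for model ", model@symbol, " with ic [",
           paste(signif(ic, 6), collapse = ", "), "]", call. = FALSE)
    out
  }
  if (config@interpolation == "dense") {
    vals <- unname(solveAt(grid)[, -1, drop = FALSE])
  } else {
    fine <- .sampleTimes(model@tMax, 4L * s)
    sol <- solveAt(fine)
    vals <- vapply(seq_len(model@dim), function(j) {
      if (config@interpolation == "cubic")
        stats::spline(fine, sol[, j + 1], xout = grid)$y
      else stats::approx(fine, sol[, j + 1], xout = grid)$y
    }, numeric(s))
    vals <- matrix(vals, nrow = s)
  }
  new("Trajectory", modelSymbol = model@symbol,
      runIndex = as.integer(runIndex), seed = as.integer(seed),
      ic = as.numeric(ic), times = grid, values = vals)
}

#' Evaluate an explicit model on the benchmark grid
#'
#' Direct (closed-form) evaluation of a quasi-periodic signal at the
#' equidistant sample times, with the given phase offset in place of the
#' canonical `x0 = 2*pi`.
#'
#' @inheritParams integrateModel
#' @param phase scalar phase offset.
#' @return a one-column [Trajectory-class].
#' @export
evaluateExplicit <- function(model, phase, config = generatorConfig(),
                             runIndex = 1L, seed = NA_integer_) {
  stopifnot(is(model, "ModelSpec"))
  if (model@form != "explicit")
    stop("evaluateExplicit() needs an explicit model", call. = FALSE)
  grid <- .sampleTimes(model@tMax, config@samples)
  vals <- matrix(explicitValue(model, grid, phase), ncol = 1)
  new("Trajectory", modelSymbol = model@symbol,
      runIndex = as.integer(runIndex), seed = as.integer(seed),
      ic = as.numeric(phase), times = grid, values = vals)
}

## One augmented run: seed the RNG with the child seed, randomize the IC,
## simulate; on divergence redraw the IC from the same stream up to the
## retry budget.
.simulateRun <- function(model, config, runIndex, seed) {
  set.seed(seed)
  retries <- 0L
  repeat {
    ic <- randomizeIC(model@x0)
    traj <- if (model@form == "ode") {
      try(integrateModel(model, ic, config, runIndex, seed), silent = TRUE)
    } else {
      evaluateExplicit(model, ic, config, runIndex, seed)
    }
    if (!inherits(traj, "try-error")) return(list(traj = traj, retries = retries))
    retries <- retries + 1L
    if (retries > config@retryBudget)
      stop("run ", runIndex, " of ", model@symbol, " exceeded the retry ",
           "budget (", config@retryBudget, ")", call. = FALSE)
    message("retrying ", model@symbol, " run ", runIndex,
            " after divergence (attempt ", retries, ")")
  }
}

#' Generate the benchmark dataset
#'
#' Produces `runsPerModel` trajectories per model with independently
#' randomized initial conditions (explicit models randomize the scalar phase
#' by the same uniform rule), optionally writing one CSV file per run in the
#' published layout. The manifest records the derived child seed, initial
#' condition and retry count of every run; the same `masterSeed` and
#' configuration reproduce the output byte for byte.
#'
#' @param models character vector of model symbols (default: all 15).
#' @param config a [GeneratorConfig-class].
#' @param dir output directory for CSV files, or `NULL` for an in-memory
#'   build.
#' @param keep keep trajectories in the returned manifest (default: `TRUE`
#'   when `dir` is `NULL`).
#' @param dryRun when `TRUE`, only the manifest (models, seeds, planned
#'   paths, counts) is computed; no simulation runs.
#' @return a [GenerationManifest-class].
#' @examples
#' m <- generateDataset("OSC_1", generatorConfig(runsPerModel = 3,
#'                                               masterSeed = 7))
#' nItems(m)          # 3 runs
#' dim(trajectoryValues(m@trajectories[[1]]))  # 1000 x 2
#' @export
generateDataset <- function(models = names(modelRegistry()),
                            config = generatorConfig(), dir = NULL,
                            keep = is.null(dir), dryRun = FALSE) {
  reg <- modelRegistry()
  bad <- setdiff(models, names(reg))
  if (length(bad)) stop("unknown model symbols: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!is.null(dir) && !dryRun) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  }
  rows <- list()
  trajs <- list()
  ics <- list()
  for (sym in models) {
    model <- reg[[sym]]
    midx <- match(sym, names(reg))
    modelDir <- if (is.null(dir)) NA_character_ else file.path(dir, sym)
    if (!is.null(dir) && !dryRun && !dir.exists(modelDir))
      dir.create(modelDir)
    for (run in seq_len(config@runsPerModel)) {
      seed <- childSeed(config@masterSeed, midx, run)
      path <- if (is.null(dir)) NA_character_ else
        file.path(modelDir, .runFileName(sym, run))
      retries <- 0L
      ic <- rep(NA_real_, model@dim)
      if (!dryRun) {
        res <- .simulateRun(model, config, run, seed)
        retries <- res$retries
        ic <- res$traj@ic
        if (!is.null(dir)) writeRun(res$traj, modelDir)
        if (keep) trajs[[length(trajs) + 1L]] <- res$traj
      }
      ics[[length(ics) + 1L]] <- ic
      rows[[length(rows) + 1L]] <- data.frame(
        model = sym, run = run, seed = seed, retries = retries,
        file = path, stringsAsFactors = FALSE)
    }
  }
  runs <- do.call(rbind, rows)
  runs$ic <- ics
  man <- new("GenerationManifest", runs = runs, models = models,
             config = config,
             dir = if (is.null(dir)) NA_character_ else dir,
             trajectories = trajs)
  if (!is.null(dir) && !dryRun) writeManifest(man, dir)
  man
}

#' Dataset counts implied by a manifest
#'
#' Pure arithmetic over the registry: number of models, files per model,
#' rows per file, and total univariate series (`sum of model dims x
#' runsPerModel`; 33,000 at the full default configuration).
#'
#' @param manifest a [GenerationManifest-class].
#' @return named list of counts.
#' @export
datasetCounts <- function(manifest) {
  stopifnot(is(manifest, "GenerationManifest"))
  reg <- modelRegistry()
  dims <- vapply(manifest@models, function(s) reg[[s]]@dim, 1L)
  list(
    nModels = length(manifest@models),
    filesPerModel = manifest@config@runsPerModel,
    rowsPerFile = manifest@config@samples,
    nFiles = length(manifest@models) * manifest@config@runsPerModel,
    nSeries = sum(dims) * manifest@config@runsPerModel
  )
}

#' Collect univariate signals from a generated dataset
#'
#' Flattens trajectories into one univariate signal per state variable
#' ("each state variable is a single signal"), with provenance and the
#' chaos/non-chaos label derived from the model's behaviour class.
#'
#' @param x a [GenerationManifest-class] with kept trajectories, or a dataset
#'   directory written by [generateDataset()].
#' @param models optional subset of model symbols.
#' @return a [SignalSet-class].
#' @export
collectSignals <- function(x, models = NULL) {
  reg <- modelRegistry()
  if (is(x, "GenerationManifest")) {
    if (!length(x@trajectories))
      stop("manifest holds no trajectories; re-generate with keep = TRUE ",
           "or read from the dataset directory", call. = FALSE)
    trajs <- x@trajectories
  } else if (is.character(x) && dir.exists(x)) {
    man <- readManifest(x)
    trajs <- lapply(seq_len(nrow(man$runs)), function(i) {
      rf <- readRun(man$runs$file[i])
      new("Trajectory", modelSymbol = rf@modelSymbol,
          runIndex = rf@runIndex, seed = as.integer(man$runs$seed[i]),
          ic = as.numeric(unlist(man$runs$ic[i])),
          times = .sampleTimes(reg[[rf@modelSymbol]]@tMax, nrow(rf@values)),
          values = rf@values)
    })
  } else stop("x must be a GenerationManifest or a dataset directory",
              call. = FALSE)
  if (!is.null(models))
    trajs <- Filter(function(t) t@modelSymbol %in% models, trajs)
  info <- list()
  sigs <- list()
  for (tr in trajs) {
    cls <- reg[[tr@modelSymbol]]@behaviourClass
    lab <- if (cls == "chaotic") "chaos" else "non_chaos"
    for (j in seq_len(ncol(tr@values))) {
      info[[length(info) + 1L]] <- data.frame(
        model = tr@modelSymbol, run = tr@runIndex, var = j,
        class = cls, label = lab, stringsAsFactors = FALSE)
      sigs[[length(sigs) + 1L]] <- tr@values[, j]
    }
  }
  new("SignalSet", info = do.call(rbind, info), signals = sigs)
}

setMethod("trajectoryValues", "Trajectory", function(object) object@values)
setMethod("trajectoryTimes", "Trajectory", function(object) object@times)
setMethod("nItems", "GenerationManifest", function(object) nrow(object@runs))
setMethod("nItems", "SignalSet", function(object) length(object@signals))

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory %s run %d: %d samples x %d variables on [0, %g]\n",
              object@modelSymbol, object@runIndex, nrow(object@values),
              ncol(object@values), max(object@times)))
})

setMethod("show", "GenerationManifest", function(object) {
  cnt <- datasetCounts(object)
  cat(sprintf(paste0("GenerationManifest: %d models x %d runs (%d files, ",
                     "%d univariate series), seed %d\n"),
              cnt$nModels, cnt$filesPerModel, cnt$nFiles, cnt$nSeries,
              object@config@masterSeed))
  if (!is.na(object@dir)) cat("  written to:", object@dir, "\n")
})

setMethod("show", "SignalSet", function(object) {
  cat(sprintf("SignalSet: %d univariate signals from %d models\n",
              nItems(object), length(unique(object@info$model))))
})
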