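## Registry of the 15 benchmark systems. Parameter values, canonical initial
## conditions and integration horizons follow the published model tables
## exactly; beta = 8/3 for the Lorenz attractor is kept as the evaluated
## rational in double precision.

.modelSpec <- function(symbol, name, class, dim, params, x0, tMax, form, eqns) {
  new("ModelSpec",
    symbol = symbol, name = name, behaviourClass = class,
    dim = as.integer(dim), params = params, x0 = as.numeric(x0),
    tMax = as.numeric(tMax), form = form, equations = eqns)
}

.buildRegistry <- function() {
  list(
    .modelSpec("CHA_1", "Ueda oscillator", "chaotic", 2,
      c(b = 0.05, A = 7.5, Omega = 1), c(2.5, 0), 100, "ode",
      c("dx1 = x2",
        "dx2 = -x1^3 - b*x2 + A*sin(Omega*t)")),
    .modelSpec("CHA_2", "Lorenz attractor", "chaotic", 3,
      c(sigma = 10, beta = 8 / 3, rho = 28), c(10, 200, 10), 100, "ode",
      c("dx1 = -sigma*x1 + sigma*x2",
        "dx2 = rho*x1 - x2 - x1*x3",
        "dx3 = -beta*x3 + x1*x2")),
    .modelSpec("CHA_3", "Roessler attractor", "chaotic", 3,
      c(a = 0.2, b = 0.2, c = 5.7), c(-9, 0, 0), 300, "ode",
      c("dx1 = -x2 - x3",
        "dx2 = x1 + a*x2",
        "dx3 = b + x3*(x1 - c)")),
    .modelSpec("CHA_4", "Halvorsen attractor", "chaotic", 3,
      c(a = 1.27), c(-5, 0, 0), 50, "ode",
      c("dx1 = -a*x1 - 4*x2 - 4*x3 - x2^2",
        "dx2 = -4*x1 - a*x2 - 4*x3 - x3^2",
        "dx3 = -4*x1 - 4*x2 - a*x3 - x1^2")),
    .modelSpec("CHA_5", "Rucklidge attractor", "chaotic", 3,
      c(k = 2, lambda = 6.7), c(1, 0, 4.5), 150, "ode",
      c("dx1 = -k*x1 + lambda*x2 - x2*x3",
        "dx2 = x1",
        "dx3 = -x3 + x2^2")),
    .modelSpec("OSC_1", "Undamped oscillator 1", "periodic", 2,
      c(a = 0.5, b = -0.5), c(1, 1), 100, "ode",
      c("dx1 = a*x2",
        "dx2 = b*x1")),
    .modelSpec("OSC_2", "Undamped oscillator 2", "periodic", 2,
      c(a = 0.5, b = -0.5), c(0.9, -0.9), 250, "ode",
      c("dx1 = a*x2",
        "dx2 = b*x1")),
    .modelSpec("DOSC_1", "Damped oscillator 1", "periodic", 2,
      numeric(0), c(1, 1), 100, "ode",
      c("dx1 = x2",
        "dx2 = -0.2*x1 - 0.08*x2 + 0.01")),
    .modelSpec("DOSC_2", "Damped oscillator 2", "periodic", 2,
      numeric(0), c(0.4, 0.3), 100, "ode",
      c("dx1 = x2",
        "dx2 = -0.04*x1 - 0.016*x2 + 0.01")),
    .modelSpec("IOSC", "Rising oscillator", "periodic", 2,
      numeric(0), c(0.1, 0.1), 100, "ode",
      c("dx1 = x2",
        "dx2 = -0.2*x1 + 0.08*x2 + 0.01")),
    .modelSpec("QPS_1", "Quasi-periodic 1", "quasi-periodic", 1,
      c(omega1 = pi), 2 * pi, 1000, "explicit",
      "x = cos(omega1*t/50 + x0) + cos(t/50 + x0)"),
    .modelSpec("QPS_2", "Quasi-periodic 2", "quasi-periodic", 1,
      c(omega1 = (1 + sqrt(5)) / 2), 2 * pi, 1000, "explicit",
      "x = sin(omega1*t/15 + x0) + sin(t/15 + x0)"),
    .modelSpec("QPS_3", "Quasi-periodic 3", "quasi-periodic", 1,
      c(omega1 = exp(1)), 2 * pi, 1000, "explicit",
      "x = sin(omega1*t/15 + x0) + cos(t/15 + x0)"),
    .modelSpec("DS_1", "Damped system 1", "non-periodic", 3,
      numeric(0), c(1.8, 2.3, 3), 100, "ode",
      c("dx1 = -0.01*x1 + 0.01*x2",
        "dx2 = -0.001*x1 - 0.01*x2",
        "dx3 = 0.05*x1 - 0.03*x3")),
    .modelSpec("DS_2", "Damped system 2", "non-periodic", 3,
      numeric(0), c(3, -1, 2), 100, "ode",
      c("dx1 = -0.05*x1 + 0.01*x2",
        "dx2 = -0.001*x1 - 0.01*x2",
        "dx3 = 0.05*x1 - 0.08*x3"))
  )
}

.registryCache <- new.env(parent = emptyenv())

#' The benchmark model registry
#'
#' Returns the 15 dynamical systems of the benchmark: 5 chaotic (`CHA_1` Ueda,
#' `CHA_2` Lorenz, `CHA_3` Roessler, `CHA_4` Halvorsen, `CHA_5` Rucklidge),
#' 5 periodic linear oscillators (`OSC_1`, `OSC_2`, `DOSC_1`, `DOSC_2`,
#' `IOSC`), 3 explicit quasi-periodic signals with irrational frequency
#' ratios (`QPS_1`..`QPS_3`), and 2 non-periodic damped linear systems
#' (`DS_1`, `DS_2`). Ordering is fixed (chaotic, periodic, quasi-periodic,
#' non-periodic as listed above), so the registry is a stable enumeration of
#' the benchmark.
#'
#' @return named list of [ModelSpec-class] objects.
#' @examples
#' reg <- modelRegistry()
#' length(reg)                      # 15
#' sum(vapply(reg, function(m) m@dim, 1L))  # 33 univariate signals per run set
#' @export
modelRegistry <- function() {
  if (is.null(.registryCache$reg)) .registryCache$reg <- .buildRegistry()
  reg <- .registryCache$reg
  names(reg) <- vapply(reg, function(m) m@symbol, character(1))
  reg
}

#' Look up one model by symbol
#'
#' @param symbol model symbol, e.g. `"CHA_2"`.
#' @return a [ModelSpec-class].
#' @export
getModel <- function(symbol) {
  reg <- modelRegistry()
  if (!symbol %in% names(reg))
    stop("unknown model symbol: ", symbol, call. = FALSE)
  reg[[symbol]]
}

#' Right-hand side of an ODE model
#'
#' Evaluates the state derivatives of an ODE-form model at time `t` and state
#' `x`. A pure function of `(t, x)`; time enters only for the periodically
#' forced Ueda oscillator (`CHA_1`).
#'
#' @param model a [ModelSpec-class] with `form == "ode"`.
#' @param t time (finite scalar).
#' @param x numeric state vector of length `model@dim`.
#' @return numeric derivative vector of the same length.
#' @examples
#' modelRHS(getModel("CHA_2"), 0, c(1, 1, 1))  # c(0, 26, -5/3)
#' @export
modelRHS <- function(model, t, x) {
  stopifnot(is(model, "ModelSpec"))
  if (model@form != "ode")
    stop("modelRHS() is only defined for ODE-form models", call. = FALSE)
  if (length(x) != model@dim)
    stop("state vector has length ", length(x), ", expected ", model@dim,
         call. = FALSE)
  p <- model@params
  switch(model@symbol,
    CHA_1 = c(x[2],
              -x[1]^3 - p[["b"]] * x[2] + p[["A"]] * sin(p[["Omega"]] * t)),
    CHA_2 = c(-p[["sigma"]] * x[1] + p[["sigma"]] * x[2],
              p[["rho"]] * x[1] - x[2] - x[1] * x[3],
              -p[["beta"]] * x[3] + x[1] * x[2]),
    CHA_3 = c(-x[2] - x[3],
              x[1] + p[["a"]] * x[2],
              p[["b"]] + x[3] * (x[1] - p[["c"]])),
    CHA_4 = {
      a <- p[["a"]]
      c(-a * x[1] - 4 * x[2] - 4 * x[3] - x[2]^2,
        -4 * x[1] - a * x[2] - 4 * x[3] - x[3]^2,
        -4 * x[1] - 4 * x[2] - a * x[3] - x[1]^2)
    },
    CHA_5 = c(-p[["k"]] * x[1] + p[["lambda"]] * x[2] - x[2] * x[3],
              x[1],
              -x[3] + x[2]^2),
    OSC_1 = ,
    OSC_2 = c(p[["a"]] * x[2], p[["b"]] * x[1]),
    DOSC_1 = c(x[2], -0.2 * x[1] - 0.08 * x[2] + 0.01),
    DOSC_2 = c(x[2], -0.04 * x[1] - 0.016 * x[2] + 0.01),
    IOSC = c(x[2], -0.2 * x[1] + 0.08 * x[2] + 0.01),
    DS_1 = c(-0.01 * x[1] + 0.01 * x[2],
             -0.001 * x[1] - 0.01 * x[2],
             0.05 * x[1] - 0.03 * x[3]),
    DS_2 = c(-0.05 * x[1] + 0.01 * x[2],
             -0.001 * x[1] - 0.01 * x[2],
             0.05 * x[1] - 0.08 * x[3]),
    stop("no right-hand side registered for ", model@symbol, call. = FALSE)
  )
}

#' Evaluate an explicit (quasi-periodic) signal
#'
#' The three quasi-periodic models are sums of two unit-amplitude sinusoids
#' whose angular-frequency ratio is irrational (pi, the golden ratio, e), so
#' the signal never repeats exactly and its value is bounded by 2 in absolute
#' magnitude. The canonical phase offset `x0 = 2*pi` is replaced by a
#' randomized phase during augmentation.
#'
#' @param model a [ModelSpec-class] with `form == "explicit"`.
#' @param t time, scalar or vector.
#' @param phase phase offset (takes the role of `x0` in the formulas).
#' @return numeric signal values, `|x| <= 2`.
#' @examples
#' explicitValue(getModel("QPS_1"), 0, 0)  # 2
#' @export
explicitValue <- function(model, t, phase) {
  stopifnot(is(model, "ModelSpec"))
  if (model@form != "explicit")
    stop("explicitValue() is only defined for explicit models", call. = FALSE)
  w1 <- model@params[["omega1"]]
  switch(model@symbol,
    QPS_1 = cos(w1 * t / 50 + phase) + cos(t / 50 + phase),
    QPS_2 = sin(w1 * t / 15 + phase) + sin(t / 15 + phase),
    QPS_3 = sin(w1 * t / 15 + phase) + cos(t / 15 + phase),
    stop("no formula registered for ", model@symbol, call. = FALSE)
  )
}

#' Serialize the registry to a YAML document
#'
#' One block per model (symbol, class, dimension, parameters, canonical
#' initial condition, horizon, and the equations as text) so documentation
#' and code cannot drift apart.
#'
#' @param path output file; when `NULL` the YAML string is returned.
#' @return the YAML string, invisibly when written to a file.
#' @export
registryToYAML <- function(path = NULL) {
  blocks <- lapply(modelRegistry(), function(m) {
    list(symbol = m@symbol, name = m@name, class = m@behaviourClass,
         dim = m@dim,
         params = as.list(m@params),
         x0 = m@x0, t_max = m@tMax, form = m@form,
         equations = as.list(m@equations))
  })
  txt <- yaml::as.yaml(unname(blocks))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec %s (%s), %s, dim %d, T_max %g\n",
              object@symbol, object@name, object@behaviourClass,
              object@dim, object@tMax))
  if (length(object@params))
    cat("  params:", paste(names(object@params), signif(object@params, 6),
                           sep = "=", collapse = ", "), "\n")
  cat("  x0:", paste(signif(object@x0, 6), collapse = ", "), "\n")
  for (e in object@equations) cat("  ", e, "\n", sep = "")
})
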