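## Derivative-based phase-portrait embedding: (x, x', x'') pseudo-state
## space for univariate signals, with second-order central differences on
## interior points.

#' Derivative-based phase-space embedding
#'
#' Builds the pseudo-state-space portrait of a univariate signal with axes
#' (signal, first-derivative approximation, second-derivative
#' approximation), the Takens-style reconstruction used for the
#' quasi-periodic phase portraits. Derivatives use second-order central
#' differences on interior points: `(f[i+1] - f[i-1]) / (2 dt)` and
#' `(f[i+1] - 2 f[i] + f[i-1]) / dt^2`, so a length-`n` signal yields
#' `n - 2` portrait points and the truncation error is O(dt^2).
#'
#' @param signal numeric vector, length at least 3.
#' @param dt positive sampling interval.
#' @return an [EmbeddedPortrait-class].
#' @examples
#' t <- seq(0, 2 * pi, by = 0.01)
#' p <- derivativeEmbed(sin(t), 0.01)   # columns approx sin, cos, -sin
#' @export
derivativeEmbed <- function(signal, dt) {
  if (length(signal) < 3L)
    stop("derivativeEmbed() needs at least 3 samples", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a positive scalar", call. = FALSE)
  n <- length(signal)
  i <- 2:(n - 1L)
  d1 <- (signal[i + 1L] - signal[i - 1L]) / (2 * dt)
  d2 <- (signal[i + 1L] - 2 * signal[i] + signal[i - 1L]) / dt^2
  pts <- cbind(x = signal[i], dx = d1, d2x = d2)
  new("EmbeddedPortrait", points = pts, dt = dt)
}

#' Portrait points accessor
#'
#' @param object an [EmbeddedPortrait-class].
#' @return the `(n-2) x 3` point matrix.
#' @export
portraitPoints <- function(object) {
  stopifnot(is(object, "EmbeddedPortrait"))
  object@points
}

#' Plot a phase portrait to a file
#'
#' Writes the three 2-D projections of the embedded portrait
#' ((x, x'), (x, x''), (x', x'')) as a PNG figure, mirroring the portrait
#' column of the model tables.
#'
#' @param portrait an [EmbeddedPortrait-class].
#' @param file output PNG path.
#' @param title figure title.
#' @return `file`, invisibly.
#' @export
plotPortrait <- function(portrait, file, title = "phase portrait") {
  stopifnot(is(portrait, "EmbeddedPortrait"))
  p <- portrait@points
  grDevices::png(file, width = 1200, height = 420)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 3), mar = c(4, 4, 3, 1))
  graphics::plot(p[, 1], p[, 2], type = "l", xlab = "x", ylab = "x'",
                 main = title)
  graphics::plot(p[, 1], p[, 3], type = "l", xlab = "x", ylab = "x''",
                 main = "")
  graphics::plot(p[, 2], p[, 3], type = "l", xlab = "x'", ylab = "x''",
                 main = "")
  invisible(file)
}

setMethod("show", "EmbeddedPortrait", function(object) {
  cat(sprintf("EmbeddedPortrait: %d points, dt = %g\n",
              nrow(object@points), object@dt))
})
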