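## Independent oracles, written directly from the printed state equations —
## deliberately not reusing the package's registry equations.

## Linear systems dx = A x + c
linearSystems <- function() {
  list(
    OSC_1 = list(A = rbind(c(0, 0.5), c(-0.5, 0)), c = c(0, 0)),
    OSC_2 = list(A = rbind(c(0, 0.5), c(-0.5, 0)), c = c(0, 0)),
    DOSC_1 = list(A = rbind(c(0, 1), c(-0.2, -0.08)), c = c(0, 0.01)),
    DOSC_2 = list(A = rbind(c(0, 1), c(-0.04, -0.016)), c = c(0, 0.01)),
    IOSC = list(A = rbind(c(0, 1), c(-0.2, 0.08)), c = c(0, 0.01)),
    DS_1 = list(A = rbind(c(-0.01, 0.01, 0),
                          c(-0.001, -0.01, 0),
                          c(0.05, 0, -0.03)), c = c(0, 0, 0)),
    DS_2 = list(A = rbind(c(-0.05, 0.01, 0),
                          c(-0.001, -0.01, 0),
                          c(0.05, 0, -0.08)), c = c(0, 0, 0))
  )
}

## Matrix-exponential solution of dx = A x + c:
## x(t) = expm(A t) (x0 - xp) + xp with A xp = -c.
linearSolution <- function(sys, x0, times) {
  xp <- if (all(sys$c == 0)) rep(0, length(x0)) else solve(sys$A, -sys$c)
  t(vapply(times, function(t) {
    as.numeric(Matrix::expm(sys$A * t) %*% (x0 - xp)) + xp
  }, numeric(length(x0))))
}

## Quasi-periodic formula values computed independently with 50-digit
## arithmetic (mpmath), frozen; columns t, phase, value.
qpsReference <- function() {
  list(
    QPS_1 = rbind(
      c(0.5, -3.7, -1.7176800010795992854),
      c(123.456, 2.1, -1.0508294423611794896),
      c(500, 0.25, 0.29051857123679948863),
      c(999.5, -1.0, 1.503758387405839836)),
    QPS_2 = rbind(
      c(0.5, -3.7, 0.98462309985420929938),
      c(123.456, 2.1, -0.49999821751895181999),
      c(500, 0.25, 0.1258223593239997762),
      c(999.5, -1.0, 0.33444094304608300968)),
    QPS_3 = rbind(
      c(0.5, -3.7, -0.41436493004777260036),
      c(123.456, 2.1, -1.2304667415711478377),
      c(500, 0.25, -0.31754666363441404526),
      c(999.5, -1.0, -1.8137976220716282199))
  )
}
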