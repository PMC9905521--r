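mkSegs <- function(values, labels) {
  n <- nrow(values)
  new("LabelledSegmentSet", values = values,
      label = factor(labels, levels = c("non_chaos", "chaos")),
      source = data.frame(model = rep_len(as.character(labels), n),
                          run = seq_len(n), var = rep_len(1L, n),
                          segment = rep_len(1L, n)))
}

## linearly separable toy problem: flat signals near 0 vs near 2
toySets <- function(n = 1200, Y = 20, seed = 1) {
  set.seed(seed)
  lab <- rep(c("non_chaos", "chaos"), n / 2)
  v <- t(vapply(lab, function(l) {
    rnorm(Y, mean = if (l == "chaos") 2 else 0, sd = 0.1)
  }, numeric(Y)))
  idx <- sample(n)
  list(train = mkSegs(v[idx[1:(0.75 * n)], ], lab[idx[1:(0.75 * n)]]),
       val = mkSegs(v[idx[(0.75 * n + 1):n], , drop = FALSE],
                    lab[idx[(0.75 * n + 1):n]]))
}

test_that("architectures have the expected parameter counts and shapes", {
  ## LSTM, 4 units, univariate input: 4*(4*(1+4)+4) + (4*2+2) = 106
  lst <- buildClassifier(classifierConfig("lstm", segmentLength = 50))
  expect_equal(paramCount(lst), 106L)
  ## valid convolution: kernel 3 on 50 samples leaves 48 positions,
  ## so the dense layer sees 48 x 32 flattened features
  cnn <- buildClassifier(classifierConfig("cnn", segmentLength = 50))
  expect_equal(dim(cnn@params$W1), c(3L, 1L, 32L))
  expect_equal(nrow(cnn@params$Wd), 48L * 32L)
  ## deep variant stacks 32/64/64 filters
  dcn <- buildClassifier(classifierConfig("cnn_deep", segmentLength = 50))
  expect_equal(dim(dcn@params$W2), c(3L, 32L, 64L))
  expect_equal(nrow(dcn@params$Wd), (50L - 3L * 2L) * 64L)
  for (cl in list(lst, cnn, dcn)) {
    p <- predictProb(cl, matrix(rnorm(7 * 50), 7))
    expect_equal(dim(p), c(7L, 2L))
    expect_true(all(p >= 0 & p <= 1))
  }
  expect_error(predictProb(lst, matrix(rnorm(7 * 60), 7)), "expects")
})

test_that("untrained classifiers sit at chance on balanced data", {
  set.seed(14)
  lab <- rep(c("non_chaos", "chaos"), 400)
  segs <- mkSegs(matrix(rnorm(800 * 50), 800), lab)
  for (arch in c("lstm", "cnn")) {
    cl <- buildClassifier(classifierConfig(arch, segmentLength = 50,
                                           trainSeed = 2))
    cc <- evaluateClassifier(cl, segs)
    expect_gt(accuracy(cc), 0.4)
    expect_lt(accuracy(cc), 0.6)
  }
})

test_that("analytic gradients match finite differences (LSTM)", {
  set.seed(42)
  n <- 3; T <- 6; u <- 2
  X <- matrix(rnorm(n * T), n)
  Y <- cbind(c(1, 0, 1), c(0, 1, 0))
  Wx <- matrix(rnorm(4 * u) * 0.5, 1)
  Wh <- matrix(rnorm(u * 4 * u) * 0.3, u)
  b <- rnorm(4 * u) * 0.1
  Wd <- matrix(rnorm(u * 2) * 0.5, u)
  bd <- rnorm(2) * 0.1
  for (softmax in c(FALSE, TRUE)) {
    g <- chaosbench:::cpp_lstm_grad(X, Y, Wx, Wh, b, Wd, bd, 0, softmax)
    lossAt <- function(Wx., Wh., b., Wd., bd.)
      chaosbench:::cpp_lstm_grad(X, Y, Wx., Wh., b., Wd., bd., 0, softmax)$loss
    h <- 1e-6
    params <- list(Wx = Wx, Wh = Wh, b = b, Wd = Wd, bd = bd)
    for (nm in names(params)) {
      num <- vapply(seq_along(params[[nm]]), function(i) {
        up <- params; up[[nm]][i] <- up[[nm]][i] + h
        dn <- params; dn[[nm]][i] <- dn[[nm]][i] - h
        (do.call(lossAt, unname(up)) - do.call(lossAt, unname(dn))) / (2 * h)
      }, 1)
      expect_lt(max(abs(as.numeric(g[[paste0("g", nm)]]) - num)), 1e-6,
                label = paste("lstm grad", nm, "softmax =", softmax))
    }
  }
})

test_that("analytic gradients match finite differences (stacked CNN)", {
  set.seed(7)
  n <- 4; T <- 12
  X <- matrix(rnorm(n * T), n)
  Y <- cbind(c(1, 0, 1, 0), c(0, 1, 0, 1))
  mkblk <- function(k, cin, f)
    list(W = array(rnorm(k * cin * f) * 0.4, c(k, cin, f)),
         b = rnorm(f) * 0.1, gamma = runif(f, 0.5, 1.5),
         beta = rnorm(f) * 0.1, rmean = rep(0, f), rvar = rep(1, f))
  blocks <- list(mkblk(3, 1, 3), mkblk(3, 3, 4))
  d <- (T - 4) * 4
  Wd <- matrix(rnorm(d * 2) * 0.3, d)
  bd <- rnorm(2) * 0.1
  g <- chaosbench:::cpp_cnn_grad(X, Y, blocks, Wd, bd, 0, 1e-3, 0.99, FALSE)
  lossAt <- function(blocks., Wd., bd.)
    chaosbench:::cpp_cnn_grad(X, Y, blocks., Wd., bd., 0, 1e-3, 0.99,
                              FALSE)$loss
  h <- 1e-6
  for (ib in 1:2) for (nm in c("W", "b", "gamma", "beta")) {
    num <- vapply(seq_along(blocks[[ib]][[nm]]), function(i) {
      up <- blocks; up[[ib]][[nm]][i] <- up[[ib]][[nm]][i] + h
      dn <- blocks; dn[[ib]][[nm]][i] <- dn[[ib]][[nm]][i] - h
      (lossAt(up, Wd, bd) - lossAt(dn, Wd, bd)) / (2 * h)
    }, 1)
    expect_lt(max(abs(as.numeric(g$blocks[[ib]][[paste0("g", nm)]]) - num)),
              1e-6, label = paste("cnn grad block", ib, nm))
  }
  numWd <- vapply(seq_along(Wd), function(i) {
    u <- Wd; u[i] <- u[i] + h; d2 <- Wd; d2[i] <- d2[i] - h
    (lossAt(blocks, u, bd) - lossAt(blocks, d2, bd)) / (2 * h)
  }, 1)
  expect_lt(max(abs(as.numeric(g$gWd) - numWd)), 1e-6)
})

test_that("training solves a separable toy problem quickly and stably", {
  toy <- toySets()
  for (arch in c("lstm", "cnn")) {
    cfg <- classifierConfig(arch, segmentLength = 20, epochs = 5,
                            patience = NA, trainSeed = 3)
    cl <- trainClassifier(buildClassifier(cfg), toy$train, toy$val)
    hist <- cl@history
    expect_equal(max(hist$valAcc), 1.0, info = arch)
    ## optimizer sanity: training loss does not increase (tolerance 1e-3)
    ## except for minibatch jitter once converged (loss below 0.05)
    ok <- diff(hist$loss) <= 1e-3 | head(hist$loss, -1) < 0.05
    expect_true(all(ok), info = arch)
    expect_equal(accuracy(evaluateClassifier(cl, toy$val)), 1.0)
  }
})

test_that("training is reproducible under a fixed seed", {
  toy <- toySets()
  cfg <- classifierConfig("lstm", segmentLength = 20, epochs = 3,
                          patience = NA, trainSeed = 11)
  c1 <- trainClassifier(buildClassifier(cfg), toy$train, toy$val)
  c2 <- trainClassifier(buildClassifier(cfg), toy$train, toy$val)
  expect_identical(c1@params, c2@params)
  expect_identical(c1@history, c2@history)
  x <- matrix(rnorm(10 * 20), 10)
  expect_identical(predictProb(c1, x), predictProb(c2, x))
})

test_that("the softmax output head is available behind the config switch", {
  toy <- toySets()
  cfg <- classifierConfig("lstm", segmentLength = 20, epochs = 5,
                          patience = NA, outputActivation = "softmax",
                          trainSeed = 5)
  cl <- trainClassifier(buildClassifier(cfg), toy$train, toy$val)
  p <- predictProb(cl, segmentValues(toy$val))
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-10)
  expect_equal(max(cl@history$valAcc), 1.0)
})

test_that("evaluation satisfies the confusion-count partition invariants", {
  set.seed(20)
  lab <- sample(c("chaos", "non_chaos"), 300, replace = TRUE)
  segs <- mkSegs(matrix(rnorm(300 * 20), 300), lab)
  cl <- buildClassifier(classifierConfig("cnn", segmentLength = 20))
  cc <- evaluateClassifier(cl, segs)
  expect_equal(cc@tp + cc@fn, sum(lab == "chaos"))
  expect_equal(cc@tn + cc@fp, sum(lab == "non_chaos"))
  rep <- experimentReport(list(list(arch = "cnn", segment = 20, counts = cc)))
  expect_equal(rep$accuracy, accuracy(cc))
  expect_equal(rep$tp + rep$fn + rep$tn + rep$fp, 300L)
})

test_that("degenerate training inputs fail loudly", {
  toy <- toySets()
  empty <- mkSegs(matrix(numeric(0), 0, 20), character(0))
  cfg <- classifierConfig("lstm", segmentLength = 20)
  expect_error(trainClassifier(buildClassifier(cfg), empty, toy$val),
               "empty")
})
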