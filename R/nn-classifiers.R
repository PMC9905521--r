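## The two classifier families of the validation experiments, implemented on
## the package's own minibatch kernels (src/nn_kernels.cpp): an LSTM
## (input -> LSTM(units) -> dropout -> dense(2, sigmoid)) and a 1-D CNN
## (conv -> ReLU -> batch norm -> dropout blocks -> flatten ->
## dense(2, sigmoid)), trained with Adam on categorical cross-entropy.

.BN_EPS <- 1e-3
.BN_MOMENTUM <- 0.99
.ADAM_BETA1 <- 0.9
.ADAM_BETA2 <- 0.999
.ADAM_EPS <- 1e-7

#' Construct a ClassifierConfig
#'
#' @param arch `"lstm"`, `"cnn"` (one convolution block) or `"cnn_deep"`
#'   (stacked blocks, the extended CNN of experiment 2).
#' @param segmentLength input sequence length Y.
#' @param lstmUnits LSTM units (default 4, as in the published
#'   architecture).
#' @param dropoutRate dropout rate (default 0.5, as published).
#' @param convFilters filters per block; defaults to 32 for `"cnn"` and
#'   32/64/64 for `"cnn_deep"` (package choices; the original account gives
#'   figures only).
#' @param convKernel kernel width (default 3).
#' @param learningRate Adam learning rate (default 0.001, as published).
#' @param batchSize minibatch size (default 64, as published).
#' @param epochs maximum epochs (default 30; unstated originally).
#' @param patience early-stopping patience on validation loss, `NA` to
#'   disable (default 5).
#' @param outputActivation `"sigmoid"` (as printed; the cross-entropy
#'   normalizes the two scores) or `"softmax"`.
#' @param trainSeed seed controlling initialization, shuffling and dropout.
#' @return a [ClassifierConfig-class].
#' @export
classifierConfig <- function(arch = c("lstm", "cnn", "cnn_deep"),
                             segmentLength = 50L, lstmUnits = 4L,
                             dropoutRate = 0.5, convFilters = NULL,
                             convKernel = 3L, learningRate = 0.001,
                             batchSize = 64L, epochs = 30L, patience = 5L,
                             outputActivation = c("sigmoid", "softmax"),
                             trainSeed = 1L) {
  arch <- match.arg(arch)
  if (is.null(convFilters))
    convFilters <- if (arch == "cnn_deep") c(32L, 64L, 64L) else 32L
  new("ClassifierConfig", arch = arch,
      segmentLength = as.integer(segmentLength),
      lstmUnits = as.integer(lstmUnits), dropoutRate = dropoutRate,
      convFilters = as.integer(convFilters),
      convKernel = as.integer(convKernel), learningRate = learningRate,
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      patience = if (is.na(patience)) NA else as.integer(patience),
      outputActivation = match.arg(outputActivation),
      trainSeed = as.integer(trainSeed))
}

.glorot <- function(fanIn, fanOut, dims) {
  lim <- sqrt(6 / (fanIn + fanOut))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

## orthonormal rows, used for the recurrent kernel
.orthogonal <- function(nr, nc) {
  a <- matrix(rnorm(max(nr, nc) * min(nr, nc)), max(nr, nc), min(nr, nc))
  q <- qr.Q(qr(a))
  if (nr <= nc) t(q)[seq_len(nr), , drop = FALSE][, seq_len(nc), drop = FALSE]
  else q[seq_len(nr), seq_len(nc), drop = FALSE]
}

.initParams <- function(cfg) {
  if (cfg@arch == "lstm") {
    u <- cfg@lstmUnits
    b <- rep(0, 4 * u)
    b[(u + 1):(2 * u)] <- 1          # forget-gate bias starts open
    list(Wx = .glorot(1, 4 * u, c(1, 4 * u)),
         Wh = .orthogonal(u, 4 * u),
         b = b,
         Wd = .glorot(u, 2, c(u, 2)),
         bd = rep(0, 2))
  } else {
    k <- cfg@convKernel
    filters <- cfg@convFilters
    p <- list()
    cin <- 1L
    len <- cfg@segmentLength
    for (i in seq_along(filters)) {
      f <- filters[i]
      len <- len - k + 1L
      if (len < 1L) stop("segment too short for ", length(filters),
                         " convolution blocks", call. = FALSE)
      p[[paste0("W", i)]] <- .glorot(k * cin, k * f, c(k, cin, f))
      p[[paste0("b", i)]] <- rep(0, f)
      p[[paste0("gamma", i)]] <- rep(1, f)
      p[[paste0("beta", i)]] <- rep(0, f)
      p[[paste0("rmean", i)]] <- rep(0, f)
      p[[paste0("rvar", i)]] <- rep(1, f)
      cin <- f
    }
    d <- len * filters[length(filters)]
    c(p, list(Wd = .glorot(d, 2, c(d, 2)), bd = rep(0, 2)))
  }
}

#' Build an untrained classifier
#'
#' Initializes the weights of the configured architecture (Glorot-uniform
#' kernels, orthonormal recurrent kernel, forget-gate bias 1, unit
#' batch-norm scale) under the config's `trainSeed`.
#'
#' @param config a [ClassifierConfig-class].
#' @return an untrained [Classifier-class].
#' @export
buildClassifier <- function(config) {
  stopifnot(is(config, "ClassifierConfig"))
  set.seed(config@trainSeed)
  new("Classifier", config = config, params = .initParams(config),
      trained = FALSE,
      history = data.frame(epoch = integer(), loss = numeric(),
                           acc = numeric(), valLoss = numeric(),
                           valAcc = numeric()))
}

#' Number of trainable parameters
#'
#' Batch-norm running statistics are state, not trainable parameters, and
#' are excluded (as in the usual deep-learning parameter counts).
#'
#' @param classifier a [Classifier-class].
#' @return integer parameter count.
#' @examples
#' ## LSTM with 4 units on univariate input: 4*(4*(1+4)+4) + (4*2+2) = 106
#' paramCount(buildClassifier(classifierConfig("lstm")))
#' @export
paramCount <- function(classifier) {
  stopifnot(is(classifier, "Classifier"))
  p <- classifier@params
  keep <- !grepl("^r(mean|var)", names(p))
  sum(vapply(p[keep], length, 1L))
}

.cnnBlocks <- function(params, nBlocks) {
  lapply(seq_len(nBlocks), function(i) list(
    W = params[[paste0("W", i)]], b = params[[paste0("b", i)]],
    gamma = params[[paste0("gamma", i)]],
    beta = params[[paste0("beta", i)]],
    rmean = params[[paste0("rmean", i)]],
    rvar = params[[paste0("rvar", i)]]))
}

#' Class-membership scores
#'
#' Forward pass without dropout (batch norm uses its running statistics).
#' Column 1 scores the non-chaos class, column 2 the chaos class.
#'
#' @param classifier a [Classifier-class].
#' @param x `n x Y` matrix of segments.
#' @return `n x 2` matrix of scores in `[0, 1]`.
#' @export
predictProb <- function(classifier, x) {
  stopifnot(is(classifier, "Classifier"))
  cfg <- classifier@config
  x <- as.matrix(x)
  if (ncol(x) != cfg@segmentLength)
    stop("segments have length ", ncol(x), ", classifier expects ",
         cfg@segmentLength, call. = FALSE)
  p <- classifier@params
  softmax <- cfg@outputActivation == "softmax"
  if (cfg@arch == "lstm")
    cpp_lstm_predict(x, p$Wx, p$Wh, p$b, p$Wd, p$bd, softmax)
  else
    cpp_cnn_predict(x, .cnnBlocks(p, length(cfg@convFilters)), p$Wd, p$bd,
                    .BN_EPS, softmax)
}

#' Predicted class labels
#'
#' Argmax over the two output scores; chaos is the positive class.
#'
#' @inheritParams predictProb
#' @return factor with levels `non_chaos`, `chaos`.
#' @export
predictClasses <- function(classifier, x) {
  p <- predictProb(classifier, x)
  factor(ifelse(p[, 2] > p[, 1], "chaos", "non_chaos"),
         levels = c("non_chaos", "chaos"))
}

.oneHot <- function(label) {
  cbind(nonchaos = as.numeric(label == "non_chaos"),
        chaos = as.numeric(label == "chaos"))
}

.lossFromProbs <- function(p, y, softmax) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)   # clip before normalizing
  if (!softmax) p <- p / rowSums(p)
  mean(-rowSums(y * log(p)))
}

#' Train a classifier
#'
#' Minibatch Adam on categorical cross-entropy (the published setup:
#' learning rate 0.001, batch size 64), with per-epoch training and
#' validation history, optional early stopping on validation loss
#' (restoring the best weights), and reproducible shuffling/dropout under
#' the config's `trainSeed`.
#'
#' @param classifier an untrained [Classifier-class].
#' @param train,validation [LabelledSegmentSet-class] objects.
#' @param verbose print per-epoch progress.
#' @return the trained [Classifier-class] with filled history.
#' @export
trainClassifier <- function(classifier, train, validation, verbose = FALSE) {
  stopifnot(is(classifier, "Classifier"), is(train, "LabelledSegmentSet"))
  cfg <- classifier@config
  n <- nItems(train)
  if (n == 0L) stop("empty training set", call. = FALSE)
  x <- segmentValues(train)
  y <- .oneHot(segmentLabels(train))
  hasVal <- !is.null(validation) && nItems(validation) > 0L
  if (hasVal) {
    xv <- segmentValues(validation)
    yv <- .oneHot(segmentLabels(validation))
  }
  softmax <- cfg@outputActivation == "softmax"
  params <- classifier@params
  trainable <- names(params)[!grepl("^r(mean|var)", names(params))]
  shapes <- lapply(params, dim)              # NULL for plain vectors
  mState <- lapply(params[trainable], function(p) numeric(length(p)))
  vState <- mState
  step <- 0
  nBlocks <- if (cfg@arch == "lstm") 0L else length(cfg@convFilters)

  set.seed(cfg@trainSeed + 1L)
  hist <- vector("list", cfg@epochs)
  bestLoss <- Inf
  bestParams <- params
  wait <- 0L
  stoppedAt <- cfg@epochs
  for (epoch in seq_len(cfg@epochs)) {
    idx <- sample.int(n)
    epochLoss <- 0
    epochAcc <- 0
    nb <- 0L
    for (start in seq(1L, n, by = cfg@batchSize)) {
      bi <- idx[start:min(start + cfg@batchSize - 1L, n)]
      xb <- x[bi, , drop = FALSE]
      yb <- y[bi, , drop = FALSE]
      if (cfg@arch == "lstm") {
        g <- cpp_lstm_grad(xb, yb, params$Wx, params$Wh, params$b,
                           params$Wd, params$bd, cfg@dropoutRate, softmax)
        grads <- list(Wx = g$gWx, Wh = g$gWh, b = g$gb, Wd = g$gWd,
                      bd = g$gbd)
      } else {
        g <- cpp_cnn_grad(xb, yb, .cnnBlocks(params, nBlocks), params$Wd,
                          params$bd, cfg@dropoutRate, .BN_EPS, .BN_MOMENTUM,
                          softmax)
        grads <- list(Wd = g$gWd, bd = g$gbd)
        for (i in seq_len(nBlocks)) {
          bg <- g$blocks[[i]]
          grads[[paste0("W", i)]] <- bg$gW
          grads[[paste0("b", i)]] <- bg$gb
          grads[[paste0("gamma", i)]] <- bg$ggamma
          grads[[paste0("beta", i)]] <- bg$gbeta
          params[[paste0("rmean", i)]] <- as.numeric(bg$rmean)
          params[[paste0("rvar", i)]] <- as.numeric(bg$rvar)
        }
      }
      if (!is.finite(g$loss))
        stop("training diverged (non-finite loss) at epoch ", epoch,
             call. = FALSE)
      step <- step + 1
      for (nm in trainable) {
        gr <- as.numeric(grads[[nm]])
        mState[[nm]] <- .ADAM_BETA1 * mState[[nm]] + (1 - .ADAM_BETA1) * gr
        vState[[nm]] <- .ADAM_BETA2 * vState[[nm]] + (1 - .ADAM_BETA2) * gr^2
        mhat <- mState[[nm]] / (1 - .ADAM_BETA1^step)
        vhat <- vState[[nm]] / (1 - .ADAM_BETA2^step)
        pv <- as.numeric(params[[nm]]) -
          cfg@learningRate * mhat / (sqrt(vhat) + .ADAM_EPS)
        params[[nm]] <- if (is.null(shapes[[nm]])) pv
                        else array(pv, shapes[[nm]])
      }
      epochLoss <- epochLoss + g$loss
      epochAcc <- epochAcc + g$acc
      nb <- nb + 1L
    }
    classifier@params <- params
    valLoss <- NA_real_
    valAcc <- NA_real_
    if (hasVal) {
      pv <- predictProb(classifier, xv)
      valLoss <- .lossFromProbs(pv, yv, softmax)
      valAcc <- mean((pv[, 2] > pv[, 1]) == (yv[, 2] > yv[, 1]))
    }
    hist[[epoch]] <- data.frame(epoch = epoch, loss = epochLoss / nb,
                                acc = epochAcc / nb, valLoss = valLoss,
                                valAcc = valAcc)
    if (verbose)
      message(sprintf("epoch %d: loss %.4f acc %.4f valLoss %.4f valAcc %.4f",
                      epoch, epochLoss / nb, epochAcc / nb, valLoss, valAcc))
    if (hasVal && !is.na(cfg@patience)) {
      if (valLoss < bestLoss - 1e-6) {
        bestLoss <- valLoss
        bestParams <- params
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg@patience) {
          stoppedAt <- epoch
          break
        }
      }
    }
  }
  if (hasVal && !is.na(cfg@patience)) classifier@params <- bestParams
  classifier@trained <- TRUE
  classifier@history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  classifier
}

#' Evaluate a trained classifier on a test set
#'
#' @param classifier a trained [Classifier-class].
#' @param test a [LabelledSegmentSet-class].
#' @return a [ConfusionCounts-class] (chaos positive).
#' @export
evaluateClassifier <- function(classifier, test) {
  stopifnot(is(test, "LabelledSegmentSet"))
  pred <- predictClasses(classifier, segmentValues(test))
  confusionCounts(segmentLabels(test), pred)
}

#' Tabulate experiment results
#'
#' Builds the benchmark-style report table: one row per (architecture,
#' segment length) with accuracy and the confusion counts.
#'
#' @param results list of lists with elements `arch`, `segment`, `counts`
#'   (a [ConfusionCounts-class]).
#' @return data.frame with columns `arch`, `segment`, `accuracy`, `tp`,
#'   `fn`, `tn`, `fp`.
#' @export
experimentReport <- function(results) {
  do.call(rbind, lapply(results, function(r) data.frame(
    arch = r$arch, segment = r$segment,
    accuracy = accuracy(r$counts),
    tp = as.integer(r$counts@tp), fn = as.integer(r$counts@fn),
    tn = as.integer(r$counts@tn), fp = as.integer(r$counts@fp),
    stringsAsFactors = FALSE)))
}

setMethod("show", "Classifier", function(object) {
  cfg <- object@config
  cat(sprintf("%s classifier (Y = %d, %s): %d trainable parameters, %s\n",
              toupper(cfg@arch), cfg@segmentLength, cfg@outputActivation,
              paramCount(object),
              if (object@trained) sprintf("trained (%d epochs)",
                                          max(object@history$epoch))
              else "untrained"))
})

## ---------------------------------------------------------------------
## High-level experiment drivers
## ---------------------------------------------------------------------

#' Generate the signal batches of the validation experiments
#'
#' Builds three independently seeded generation batches: the training batch
#' of the 7 core models, a hold-out test batch of the same models with
#' fresh seeds (sized by `testRunsPerModel`, default about 0.744 of the
#' training runs, the test/train ratio of the published set sizes), and
#' optionally the quasi-periodic batch for experiment 3. Batch master seeds
#' are `masterSeed`, `masterSeed + 1` and `masterSeed + 2`.
#'
#' @param runsPerModel runs per model in the training batch (1,000 for the
#'   full benchmark, 100 for the scaled desk runs).
#' @param testRunsPerModel runs per model in the hold-out batch.
#' @param masterSeed base seed.
#' @param samples series length.
#' @param includeQPS also generate the quasi-periodic batch.
#' @return list with [SignalSet-class] elements `train`, `test`, and
#'   optionally `qps`.
#' @export
experimentSignals <- function(runsPerModel = 1000L,
                              testRunsPerModel =
                                max(1L, round(0.744 * runsPerModel)),
                              masterSeed = 1L, samples = 1000L,
                              includeQPS = FALSE) {
  em <- experimentModels()
  trainMan <- generateDataset(em$core,
    generatorConfig(runsPerModel, samples, masterSeed))
  testMan <- generateDataset(em$core,
    generatorConfig(testRunsPerModel, samples, masterSeed + 1L))
  out <- list(train = collectSignals(trainMan),
              test = collectSignals(testMan))
  if (includeQPS) {
    qpsMan <- generateDataset(em$qps,
      generatorConfig(runsPerModel, samples, masterSeed + 2L))
    out$qps <- collectSignals(qpsMan)
  }
  out
}

#' Run one validation experiment end to end
#'
#' Segments the given signal batches, assembles the experiment's
#' train/validation/test sets, trains the configured classifier (unless a
#' trained one is supplied, the usual case for experiment 3, which reuses
#' the experiment-1/-2 models), and evaluates on the test set.
#'
#' @param expId 1, 2 or 3.
#' @param arch `"lstm"`, `"cnn"` or `"cnn_deep"`.
#' @param Y segment length (50, 100 or 200).
#' @param signals list from [experimentSignals()] (must contain `qps` for
#'   experiment 3).
#' @param seed split/training seed.
#' @param variant for experiment 3: `"whole"` reuses the whole-signal
#'   segmentation of experiment 1, `"first"` the first-segment layout of
#'   experiment 2.
#' @param classifier optional pre-trained [Classifier-class] to evaluate.
#' @param epochs,patience training-schedule overrides.
#' @param balanceTest down-sample the majority class of the test batch.
#' @param verbose print training progress.
#' @return list with elements `split`, `classifier`, `counts`, `accuracy`.
#' @export
runExperiment <- function(expId, arch, Y, signals, seed = 1L,
                          variant = c("whole", "first"), classifier = NULL,
                          epochs = 30L, patience = 5L, balanceTest = FALSE,
                          verbose = FALSE) {
  expId <- as.integer(expId)
  variant <- match.arg(variant)
  mode <- if (expId == 2L || (expId == 3L && variant == "first"))
    "first_segment_only" else "all_segments"
  cfg <- segmentConfig(Y, mode)
  split <- buildExperiment(expId, signals$train, signals$test,
                           qpsSignals = signals$qps, cfg = cfg,
                           splitSeed = seed, balanceTest = balanceTest)
  if (is.null(classifier)) {
    ccfg <- classifierConfig(arch, segmentLength = Y, epochs = epochs,
                             patience = patience, trainSeed = seed)
    classifier <- trainClassifier(buildClassifier(ccfg), split@train,
                                  split@validation, verbose = verbose)
  }
  counts <- evaluateClassifier(classifier, split@test)
  list(split = split, classifier = classifier, counts = counts,
       accuracy = accuracy(counts))
}
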