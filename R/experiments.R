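## Validation experiments: segmentation, chaos/non-chaos labelling,
## optional class balancing, train/validation/test assembly, and
## confusion-matrix evaluation (chaos is always the positive class).

#' Construct a SegmentConfig
#'
#' @param length segment length Y; the benchmark uses 50, 100 or 200, which
#'   divide the series length 1,000 exactly.
#' @param mode `"all_segments"` or `"first_segment_only"`.
#' @return a [SegmentConfig-class].
#' @export
segmentConfig <- function(length = 50L,
                          mode = c("all_segments", "first_segment_only")) {
  new("SegmentConfig", length = as.integer(length), mode = match.arg(mode))
}

#' Model subsets of the validation experiments
#'
#' Experiments 1 and 2 use three chaotic systems (Ueda `CHA_1`, Lorenz
#' `CHA_2`, Roessler `CHA_3`) against four non-chaotic ones (`OSC_1`,
#' `DOSC_2`, `IOSC`, `DS_1`); experiment 3 augments the test set with the
#' three quasi-periodic signals, labelled non-chaos.
#'
#' @return list with elements `chaos`, `nonchaos`, `core` (their union) and
#'   `qps`.
#' @export
experimentModels <- function() {
  chaos <- c("CHA_1", "CHA_2", "CHA_3")
  nonchaos <- c("OSC_1", "DOSC_2", "IOSC", "DS_1")
  list(chaos = chaos, nonchaos = nonchaos, core = c(chaos, nonchaos),
       qps = c("QPS_1", "QPS_2", "QPS_3"))
}

#' Split a series into fixed-length segments
#'
#' Contiguous, non-overlapping windows from the start of the series:
#' `floor(s / Y)` windows in `"all_segments"` mode (exact division at the
#' benchmark defaults), or only window 0 in `"first_segment_only"` mode.
#' Concatenating the returned rows reproduces the input prefix.
#'
#' @param series numeric vector of length `s >= Y`.
#' @param cfg a [SegmentConfig-class].
#' @return matrix with one segment per row and `Y` columns.
#' @examples
#' nrow(segmentSeries(rnorm(1000), segmentConfig(50)))  # 20
#' @export
segmentSeries <- function(series, cfg) {
  stopifnot(is(cfg, "SegmentConfig"))
  y <- cfg@length
  if (y > length(series))
    stop("segment length ", y, " exceeds series length ", length(series),
         call. = FALSE)
  k <- if (cfg@mode == "first_segment_only") 1L else length(series) %/% y
  matrix(series[seq_len(k * y)], nrow = k, ncol = y, byrow = TRUE)
}

## Cut every signal of a SignalSet into labelled segments.
.segmentSignalSet <- function(sigset, cfg) {
  stopifnot(is(sigset, "SignalSet"))
  info <- sigset@info
  segs <- lapply(sigset@signals, segmentSeries, cfg = cfg)
  k <- vapply(segs, nrow, 1L)
  src <- data.frame(
    model = rep(info$model, k), run = rep(info$run, k),
    var = rep(info$var, k),
    segment = unlist(lapply(k, seq_len), use.names = FALSE),
    stringsAsFactors = FALSE)
  lab <- factor(rep(info$label, k), levels = c("non_chaos", "chaos"))
  new("LabelledSegmentSet", values = do.call(rbind, segs), label = lab,
      source = src)
}

## Down-sample the majority class at the whole-signal level so that the two
## classes differ by at most the larger class remainder; seeded.
.balanceSignals <- function(sigset, seed) {
  info <- sigset@info
  pos <- which(info$label == "chaos")
  neg <- which(info$label == "non_chaos")
  if (length(pos) == length(neg)) return(sigset)
  set.seed(seed)
  if (length(pos) > length(neg)) {
    keepMaj <- sort(sample(pos, length(neg)))
    keep <- sort(c(keepMaj, neg))
  } else {
    keepMaj <- sort(sample(neg, length(pos)))
    keep <- sort(c(pos, keepMaj))
  }
  new("SignalSet", info = info[keep, , drop = FALSE],
      signals = sigset@signals[keep])
}

.subsetSegments <- function(segset, idx) {
  new("LabelledSegmentSet", values = segset@values[idx, , drop = FALSE],
      label = segset@label[idx], source = segset@source[idx, , drop = FALSE])
}

.rbindSegments <- function(a, b) {
  new("LabelledSegmentSet", values = rbind(a@values, b@values),
      label = factor(c(as.character(a@label), as.character(b@label)),
                     levels = c("non_chaos", "chaos")),
      source = rbind(a@source, b@source))
}

#' Assemble one validation experiment
#'
#' Builds the train/validation/test segment sets of experiments 1-3 from
#' generated signals. Labels derive solely from the model behaviour class
#' (chaotic is the positive class). The training pool is split 75 % / 25 %
#' into train and validation at the run level (all state variables and all
#' segments of one run land in the same set), stratified by class and
#' seeded. Experiment 1 segments whole signals, experiment 2 uses only the
#' first segment of each signal, and experiment 3 reuses the experiment-1
#' (or -2) layout while augmenting the test set with all quasi-periodic
#' segments, labelled non-chaos.
#'
#' Class balancing ("counterbalancing") is optional: the 7-model subset is
#' nearly balanced by construction (8 chaotic vs 9 non-chaotic signal
#' dimensions), and the published set sizes correspond to no down-sampling.
#' With `balanceTrain`/`balanceTest` the majority class is down-sampled at
#' the whole-signal level, seeded.
#'
#' @param expId 1, 2 or 3.
#' @param trainSignals [SignalSet-class] with the 7 core models (training
#'   batch).
#' @param testSignals [SignalSet-class] with the 7 core models from an
#'   independent hold-out generation batch.
#' @param qpsSignals [SignalSet-class] with the quasi-periodic models
#'   (experiment 3 only).
#' @param cfg a [SegmentConfig-class]; its mode is forced to
#'   `"all_segments"` for experiment 1 and `"first_segment_only"` for
#'   experiment 2, and honoured as given for experiment 3.
#' @param splitSeed seed of the stratified 75/25 split.
#' @param balanceTrain,balanceTest optional majority-class down-sampling.
#' @param balanceSeed seed of the balancing draw.
#' @return an [ExperimentSplit-class].
#' @export
buildExperiment <- function(expId, trainSignals, testSignals,
                            qpsSignals = NULL, cfg = segmentConfig(50),
                            splitSeed = 1L, balanceTrain = FALSE,
                            balanceTest = FALSE, balanceSeed = splitSeed + 1L) {
  expId <- as.integer(expId)
  stopifnot(expId %in% 1:3, is(trainSignals, "SignalSet"),
            is(testSignals, "SignalSet"), is(cfg, "SegmentConfig"))
  em <- experimentModels()
  for (set in list(trainSignals, testSignals)) {
    missing <- setdiff(em$core, unique(set@info$model))
    if (length(missing))
      stop("signals missing for models: ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  if (expId == 3L && is.null(qpsSignals))
    stop("experiment 3 needs qpsSignals", call. = FALSE)
  mode <- switch(expId, "all_segments", "first_segment_only", cfg@mode)
  cfg <- segmentConfig(cfg@length, mode)

  keepCore <- function(s) {
    idx <- which(s@info$model %in% em$core)
    new("SignalSet", info = s@info[idx, , drop = FALSE],
        signals = s@signals[idx])
  }
  trainSignals <- keepCore(trainSignals)
  testSignals <- keepCore(testSignals)
  if (balanceTrain) trainSignals <- .balanceSignals(trainSignals, balanceSeed)
  if (balanceTest) testSignals <- .balanceSignals(testSignals, balanceSeed + 1L)

  ## run-level stratified 75/25 split of the training pool
  info <- trainSignals@info
  unitKey <- paste(info$model, info$run)
  units <- unique(data.frame(key = unitKey, label = info$label,
                             stringsAsFactors = FALSE))
  set.seed(splitSeed)
  valKeys <- unlist(lapply(split(units$key, units$label), function(k) {
    sample(k, round(0.25 * length(k)))
  }), use.names = FALSE)
  isVal <- unitKey %in% valKeys

  pool <- .segmentSignalSet(trainSignals, cfg)
  poolKey <- paste(pool@source$model, pool@source$run)
  valMask <- poolKey %in% valKeys
  trainSet <- .subsetSegments(pool, which(!valMask))
  valSet <- .subsetSegments(pool, which(valMask))

  testSet <- .segmentSignalSet(testSignals, cfg)
  if (expId == 3L) {
    qidx <- which(qpsSignals@info$model %in% em$qps)
    qps <- new("SignalSet", info = qpsSignals@info[qidx, , drop = FALSE],
               signals = qpsSignals@signals[qidx])
    testSet <- .rbindSegments(testSet, .segmentSignalSet(qps, cfg))
  }
  new("ExperimentSplit", expId = expId, segmentConfig = cfg,
      train = trainSet, validation = valSet, test = testSet)
}

#' Set sizes implied by the registry (pure arithmetic)
#'
#' Computes the experiment set sizes that follow from the registry and the
#' generation constants alone, without any simulation: the 7 core models
#' contribute 17 signal dimensions (8 chaotic, 9 non-chaotic), so the
#' training pool holds `17 * runsPerModel` signals, i.e. that many first
#' segments, or `17 * runsPerModel * samples / Y` whole-signal segments.
#'
#' @param Y segment length.
#' @param runsPerModel runs per model (1,000 at the full configuration).
#' @param samples series length (1,000).
#' @return named list of counts.
#' @examples
#' experimentSizes(50)$trainPoolSegments  # 340000
#' @export
experimentSizes <- function(Y, runsPerModel = 1000L, samples = 1000L) {
  reg <- modelRegistry()
  em <- experimentModels()
  dims <- vapply(reg, function(m) m@dim, 1L)
  coreDims <- sum(dims[em$core])
  chaosDims <- sum(dims[em$chaos])
  segPerSignal <- samples %/% Y
  qpsSignals <- length(em$qps) * runsPerModel
  list(
    coreDims = coreDims,
    chaosDims = chaosDims,
    nonChaosDims = coreDims - chaosDims,
    trainPoolSignals = coreDims * runsPerModel,
    trainPoolFirstSegments = coreDims * runsPerModel,
    trainPoolSegments = coreDims * runsPerModel * segPerSignal,
    qpsSignals = qpsSignals,
    qpsSegments = qpsSignals * segPerSignal
  )
}

#' Confusion counts for binary chaos classification
#'
#' @param truth,predicted factors (or characters) with values
#'   `"chaos"` / `"non_chaos"`; chaos is the positive class.
#' @return a [ConfusionCounts-class].
#' @examples
#' cc <- confusionCounts(c("chaos", "non_chaos"), c("chaos", "chaos"))
#' accuracy(cc)  # 0.5
#' @export
confusionCounts <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted),
            all(truth %in% c("chaos", "non_chaos")),
            all(predicted %in% c("chaos", "non_chaos")))
  new("ConfusionCounts",
      tp = sum(truth == "chaos" & predicted == "chaos"),
      fn = sum(truth == "chaos" & predicted == "non_chaos"),
      tn = sum(truth == "non_chaos" & predicted == "non_chaos"),
      fp = sum(truth == "non_chaos" & predicted == "chaos"))
}

#' @rdname accuracy
#' @export
setMethod("accuracy", "ConfusionCounts", function(object) {
  tot <- object@tp + object@fn + object@tn + object@fp
  if (tot == 0) return(NA_real_)
  (object@tp + object@tn) / tot
})

setMethod("segmentValues", "LabelledSegmentSet", function(object) object@values)
setMethod("segmentLabels", "LabelledSegmentSet", function(object) object@label)
setMethod("segmentSource", "LabelledSegmentSet", function(object) object@source)
setMethod("nItems", "LabelledSegmentSet", function(object) nrow(object@values))

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts (chaos positive): TP %d  FN %d  TN %d  FP %d",
              as.integer(object@tp), as.integer(object@fn),
              as.integer(object@tn), as.integer(object@fp)),
      sprintf(" | accuracy %.3f\n", accuracy(object)))
})

setMethod("show", "LabelledSegmentSet", function(object) {
  tab <- table(object@label)
  cat(sprintf("LabelledSegmentSet: %d segments of length %d (%d chaos, %d non-chaos)\n",
              nrow(object@values), ncol(object@values),
              tab[["chaos"]], tab[["non_chaos"]]))
})

setMethod("show", "ExperimentSplit", function(object) {
  cat(sprintf("ExperimentSplit (experiment %d, Y = %d, %s)\n", object@expId,
              object@segmentConfig@length, object@segmentConfig@mode))
  cat(sprintf("  train %d | validation %d | test %d segments\n",
              nItems(object@train), nItems(object@validation),
              nItems(object@test)))
})
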