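test_that("segmentation partitions a series into contiguous windows", {
  s <- seq_len(1000)
  segs <- segmentSeries(s, segmentConfig(50))
  expect_equal(dim(segs), c(20L, 50L))
  ## concatenating the rows reproduces the input
  expect_equal(as.numeric(t(segs)), s)
  expect_equal(nrow(segmentSeries(s, segmentConfig(100))), 10L)
  expect_equal(nrow(segmentSeries(s, segmentConfig(200))), 5L)
  first <- segmentSeries(s, segmentConfig(200, "first_segment_only"))
  expect_equal(dim(first), c(1L, 200L))
  expect_equal(as.numeric(first), s[1:200])
  ## non-divisible length keeps floor(s/Y) complete windows
  expect_equal(nrow(segmentSeries(seq_len(130), segmentConfig(50))), 2L)
  expect_error(segmentSeries(seq_len(30), segmentConfig(50)), "exceeds")
})

test_that("registry arithmetic gives the published experiment set sizes", {
  sz <- experimentSizes(50)
  expect_equal(sz$coreDims, 17L)            # 8 chaotic + 9 non-chaotic dims
  expect_equal(sz$chaosDims, 8L)
  expect_equal(sz$trainPoolFirstSegments, 17000L)
  expect_equal(sz$trainPoolSegments, 340000L)
  expect_equal(sz$qpsSegments, 60000L)
  expect_equal(experimentSizes(100)$trainPoolSegments, 170000L)
  expect_equal(experimentSizes(200)$trainPoolSegments, 85000L)
})

test_that("labels derive from the behaviour class, chaos positive", {
  sig <- smallSignals()
  split <- buildExperiment(1, sig$train, sig$test, cfg = segmentConfig(100),
                           splitSeed = 2)
  for (set in list(split@train, split@validation, split@test)) {
    src <- segmentSource(set)
    lab <- segmentLabels(set)
    expect_true(all(lab[grepl("^CHA_", src$model)] == "chaos"))
    expect_true(all(lab[!grepl("^CHA_", src$model)] == "non_chaos"))
  }
})

test_that("the 75/25 split is run-exclusive (no leakage) and stratified", {
  sig <- smallSignals()
  split <- buildExperiment(1, sig$train, sig$test, cfg = segmentConfig(50),
                           splitSeed = 7)
  trainKeys <- unique(paste(segmentSource(split@train)$model,
                            segmentSource(split@train)$run))
  valKeys <- unique(paste(segmentSource(split@validation)$model,
                          segmentSource(split@validation)$run))
  expect_length(intersect(trainKeys, valKeys), 0L)
  ## every segment of the pool is in exactly one of the two sets
  total <- nItems(split@train) + nItems(split@validation)
  expect_equal(total, 17 * 10 * 20)   # 17 dims x 10 runs x 20 windows
  ## validation holds ~25% of runs per class
  frac <- nItems(split@validation) / total
  expect_gt(frac, 0.15)
  expect_lt(frac, 0.35)
  ## test segments come only from the hold-out batch (disjoint by seed)
  expect_equal(nItems(split@test), 17 * 8 * 20)
})

test_that("experiment 2 keeps only first segments; experiment 3 adds QPS", {
  sig <- smallSignals()
  s2 <- buildExperiment(2, sig$train, sig$test, cfg = segmentConfig(50))
  expect_equal(nItems(s2@train) + nItems(s2@validation), 170L)
  expect_true(all(segmentSource(s2@train)$segment == 1L))
  s1 <- buildExperiment(1, sig$train, sig$test, cfg = segmentConfig(50))
  s3 <- buildExperiment(3, sig$train, sig$test, qpsSignals = sig$qps,
                        cfg = segmentConfig(50))
  expect_equal(nItems(s3@test), nItems(s1@test) + 3 * 10 * 20)
  qpsRows <- grepl("^QPS_", segmentSource(s3@test)$model)
  expect_true(all(segmentLabels(s3@test)[qpsRows] == "non_chaos"))
  expect_error(buildExperiment(3, sig$train, sig$test, cfg = segmentConfig(50)),
               "qpsSignals")
})

test_that("optional counterbalancing equalizes classes at the signal level", {
  sig <- smallSignals()
  split <- buildExperiment(1, sig$train, sig$test, cfg = segmentConfig(100),
                           splitSeed = 3, balanceTrain = TRUE,
                           balanceTest = TRUE)
  for (set in list(split@test)) {
    lab <- segmentLabels(set)
    expect_equal(sum(lab == "chaos"), sum(lab == "non_chaos"))
  }
  poolLab <- c(as.character(segmentLabels(split@train)),
               as.character(segmentLabels(split@validation)))
  expect_equal(sum(poolLab == "chaos"), sum(poolLab == "non_chaos"))
})

test_that("confusion counts and accuracy behave as defined", {
  cc <- confusionCounts(rep(c("chaos", "non_chaos"), c(3, 2)),
                        rep(c("chaos", "non_chaos"), c(3, 2)))
  expect_equal(accuracy(cc), 1.0)
  expect_equal(cc@fp + cc@fn, 0)
  cc2 <- confusionCounts(c("chaos", "chaos", "non_chaos"),
                         c("chaos", "non_chaos", "chaos"))
  expect_equal(c(cc2@tp, cc2@fn, cc2@tn, cc2@fp), c(1, 1, 0, 1))
  expect_equal(accuracy(cc2), 1 / 3)
  expect_error(confusionCounts("chaos", c("chaos", "chaos")))
})

test_that("published accuracies are consistent with their printed counts", {
  pub <- publishedResults()
  expect_equal(nrow(pub), 24L)
  recomputed <- (pub$tp + pub$tn) / (pub$tp + pub$fn + pub$tn + pub$fp)
  ## printed accuracies are rounded or truncated at 3 decimals
  expect_true(all(abs(recomputed - pub$accuracy) <= 1e-3))
  ## the flagship row: 0.978 at segment 50 for the recurrent model
  row <- pub[pub$experiment == 1 & pub$arch == "lstm" & pub$segment == 50, ]
  expect_equal(round((row$tp + row$tn) /
                     (row$tp + row$fn + row$tn + row$fp), 3), 0.978)
  ## first-segment test sets have the nominal 12,652 / 15,652 sizes
  e2 <- pub[pub$experiment == 2, ]
  expect_true(all(e2$tp + e2$fn + e2$tn + e2$fp == 12652))
  e3f <- pub[pub$experiment == 3 & pub$variant == "first", ]
  expect_true(all(e3f$tp + e3f$fn + e3f$tn + e3f$fp == 15652))
})
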