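mkTraj <- function(values, symbol = "TST", run = 1L, tMax = 1) {
  new("Trajectory", modelSymbol = symbol, runIndex = as.integer(run),
      seed = 1L, ic = values[1, ], times = seq(0, tMax,
                                               length.out = nrow(values)),
      values = values)
}

test_that("run files round-trip exactly, including awkward doubles", {
  dir <- withr::local_tempdir()
  set.seed(31)
  v <- cbind(c(pi, 1 / 3, 1e-17, -123456.789, 0, 2^-30),
             rnorm(6) * 10^runif(6, -12, 12))
  rf <- writeRun(mkTraj(v), dir)
  expect_match(basename(rf@path), "^TST_0001\\.csv$")
  back <- readRun(rf@path)
  expect_identical(back@values, unname(v))
  expect_equal(back@modelSymbol, "TST")
  expect_equal(back@runIndex, 1L)
})

test_that("run files have no header, no time column, LF line ends", {
  dir <- withr::local_tempdir()
  tr <- integrateModel(getModel("CHA_3"), c(-9, 0, 0),
                       generatorConfig(samples = 100))
  rf <- writeRun(tr, dir)
  raw <- readChar(rf@path, file.info(rf@path)$size, useBytes = TRUE)
  expect_false(grepl("\r", raw, fixed = TRUE))
  lines <- readLines(rf@path)
  expect_length(lines, 100L)
  expect_equal(lengths(strsplit(lines, ",")), rep(3L, 100))
  expect_false(is.na(suppressWarnings(as.numeric(strsplit(lines[1], ",")[[1]][1]))))
  back <- readRun(rf@path, expectedDim = 3L)
  expect_identical(back@values, trajectoryValues(tr))
})

test_that("quasi-periodic run files have exactly one column", {
  dir <- withr::local_tempdir()
  tr <- evaluateExplicit(getModel("QPS_1"), 0.5,
                         generatorConfig(samples = 50))
  rf <- writeRun(tr, dir)
  expect_equal(ncol(readRun(rf@path)@values), 1L)
})

test_that("the reader tolerates newline variants and rejects ragged rows", {
  f1 <- tempfile(fileext = ".csv")
  writeLines(c("1,2", "3,4"), f1)                 # trailing newline
  f2 <- tempfile(fileext = ".csv")
  cat("1,2\n3,4", file = f2)                      # no trailing newline
  f3 <- tempfile(fileext = ".csv")
  writeBin(charToRaw("1,2\r\n3,4\r\n"), f3)       # CRLF
  for (f in c(f1, f2, f3))
    expect_equal(readRun(f)@values, rbind(c(1, 2), c(3, 4)),
                 ignore_attr = TRUE)
  f4 <- tempfile(fileext = ".csv")
  writeLines(c("1,2", "3,4,5"), f4)
  expect_error(readRun(f4), "ragged")
  expect_error(readRun(f1, expectedDim = 3), "expected 3")
  expect_error(readRun(tempfile()), "not found")
})

test_that("a written dataset carries a faithful manifest", {
  dir <- withr::local_tempdir()
  cfg <- generatorConfig(runsPerModel = 2, samples = 50, masterSeed = 9)
  man <- generateDataset(c("OSC_1", "QPS_1"), cfg, dir = dir)
  files <- list.files(dir, pattern = "\\.csv$", recursive = TRUE)
  expect_length(files, 4L)
  back <- readManifest(dir)
  expect_equal(back$config@masterSeed, 9L)
  expect_equal(nrow(back$runs), 4L)
  expect_equal(back$runs$seed, man@runs$seed)
  expect_equal(back$runs$ic, man@runs$ic)
  ## files on disk equal in-memory values exactly
  sig <- collectSignals(dir)
  expect_equal(nItems(sig), 2L * 2L + 2L)  # 2 runs x dim 2 + 2 runs x dim 1
})

test_that("same master seed reproduces a byte-identical dataset tree", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- generatorConfig(runsPerModel = 2, samples = 100, masterSeed = 11)
  generateDataset(c("OSC_1", "DS_2"), cfg, dir = d1)
  generateDataset(c("OSC_1", "DS_2"), cfg, dir = d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    b1 <- readBin(file.path(d1, f), "raw", file.info(file.path(d1, f))$size)
    b2 <- readBin(file.path(d2, f), "raw", file.info(file.path(d2, f))$size)
    expect_identical(b1, b2, info = f)
  }
})

test_that("model archives are valid zip files with the run files inside", {
  dir <- withr::local_tempdir()
  cfg <- generatorConfig(runsPerModel = 3, samples = 50, masterSeed = 4)
  generateDataset("DOSC_1", cfg, dir = dir)
  zp <- packageModel("DOSC_1", dir)
  expect_true(file.exists(zp))
  ## the central directory lists the three run files plus the manifest slice
  listing <- utils::unzip(zp, list = TRUE)
  expect_setequal(basename(listing$Name),
                  c(sprintf("DOSC_1_%04d.csv", 1:3), "manifest.json"))
  ## extraction restores the exact bytes
  ex <- withr::local_tempdir()
  utils::unzip(zp, exdir = ex)
  for (i in 1:3) {
    f <- sprintf("DOSC_1/DOSC_1_%04d.csv", i)
    expect_identical(readBin(file.path(ex, f), "raw",
                             file.info(file.path(ex, f))$size),
                     readBin(file.path(dir, f), "raw",
                             file.info(file.path(dir, f))$size))
  }
})
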