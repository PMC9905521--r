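## Readers/writers for the published dataset layout: per-run CSV files
## (comma separated, LF line ends, no header, no time column), per-model
## store-only zip archives, and the JSON generation manifest.

.runFileName <- function(symbol, run) sprintf("%s_%04d.csv", symbol, run)

## Shortest decimal representation that parses back to the exact double:
## try 15, 16, 17 significant digits per value. Keeps files diff-stable
## across platforms.
.formatShortest <- function(x) {
  out <- sprintf("%.15g", x)
  for (digs in c("%.16g", "%.17g")) {
    bad <- as.numeric(out) != x
    if (!any(bad)) break
    out[bad] <- sprintf(digs, x[bad])
  }
  out
}

#' Write one trajectory as a CSV run file
#'
#' File name is `<symbol>_<zero-padded run>.csv`; content is one row per
#' sample, one comma-separated column per state variable, no header and no
#' time column (times are implied by `samples` and `tMax` in the manifest).
#' Numbers use the shortest decimal representation that round-trips to the
#' same double, so `readRun(writeRun(x))` is exact.
#'
#' @param trajectory a [Trajectory-class].
#' @param dir output directory.
#' @return a [RunFile-class], invisibly.
#' @export
writeRun <- function(trajectory, dir) {
  stopifnot(is(trajectory, "Trajectory"))
  if (!dir.exists(dir))
    stop("cannot write run file: directory does not exist: ", dir,
         call. = FALSE)
  path <- file.path(dir, .runFileName(trajectory@modelSymbol,
                                      trajectory@runIndex))
  v <- trajectory@values
  cols <- lapply(seq_len(ncol(v)), function(j) .formatShortest(v[, j]))
  lines <- do.call(paste, c(cols, sep = ","))
  con <- file(path, open = "wb")  # binary: LF line ends on every platform
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(new("RunFile", path = path,
                modelSymbol = trajectory@modelSymbol,
                runIndex = trajectory@runIndex, values = v))
}

#' Read a run file
#'
#' Tolerant of a missing or present trailing newline and of CRLF line ends;
#' raises an error on ragged rows or on a column-count mismatch with
#' `expectedDim`.
#'
#' @param path CSV run file.
#' @param expectedDim expected number of state-variable columns, or `NA`.
#' @return a [RunFile-class].
#' @export
readRun <- function(path, expectedDim = NA_integer_) {
  if (!file.exists(path))
    stop("run file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(parts)
  if (length(unique(nf)) != 1L)
    stop("ragged rows in run file: ", path, call. = FALSE)
  if (!is.na(expectedDim) && nf[1] != expectedDim)
    stop("run file ", path, " has ", nf[1], " columns, expected ",
         expectedDim, call. = FALSE)
  vals <- matrix(as.numeric(unlist(parts)), nrow = length(lines),
                 ncol = nf[1], byrow = TRUE)
  if (anyNA(vals))
    stop("non-numeric values in run file: ", path, call. = FALSE)
  base <- sub("\\.csv$", "", basename(path))
  runIdx <- suppressWarnings(as.integer(sub(".*_(\\d+)$", "\\1", base)))
  sym <- sub("_(\\d+)$", "", base)
  new("RunFile", path = path, modelSymbol = sym,
      runIndex = if (is.na(runIdx)) NA_integer_ else runIdx, values = vals)
}

#' Write / read the generation manifest
#'
#' `manifest.json` at the dataset root records the generator configuration
#' and, per run, the model symbol, run index, child seed, randomized initial
#' condition, retry count and file path (relative to the dataset root).
#'
#' @param manifest a [GenerationManifest-class].
#' @param dir dataset root directory.
#' @return `writeManifest` the path invisibly; `readManifest` a list with
#'   elements `config` and `runs`.
#' @export
writeManifest <- function(manifest, dir) {
  stopifnot(is(manifest, "GenerationManifest"))
  runs <- manifest@runs
  relFile <- ifelse(is.na(runs$file), NA_character_,
                    file.path(runs$model, basename(runs$file)))
  payload <- list(
    config = list(
      runsPerModel = manifest@config@runsPerModel,
      samples = manifest@config@samples,
      masterSeed = manifest@config@masterSeed,
      relTol = manifest@config@relTol,
      absTol = manifest@config@absTol,
      interpolation = manifest@config@interpolation,
      retryBudget = manifest@config@retryBudget),
    models = manifest@models,
    runs = lapply(seq_len(nrow(runs)), function(i) list(
      model = runs$model[i], run = runs$run[i], seed = runs$seed[i],
      retries = runs$retries[i], ic = runs$ic[[i]], file = relFile[i]))
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeManifest
#' @param dir dataset root directory containing `manifest.json`.
#' @export
readManifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path))
    stop("no manifest.json under ", dir, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  runs <- do.call(rbind, lapply(raw$runs, function(r) data.frame(
    model = r$model, run = r$run, seed = r$seed, retries = r$retries,
    file = file.path(dir, r$file), stringsAsFactors = FALSE)))
  runs$ic <- lapply(raw$runs, function(r) as.numeric(unlist(r$ic)))
  cfg <- raw$config
  list(config = generatorConfig(cfg$runsPerModel, cfg$samples,
                                cfg$masterSeed, cfg$relTol, cfg$absTol,
                                cfg$interpolation, cfg$retryBudget),
       models = unlist(raw$models), runs = runs)
}

## --- minimal store-only ZIP writer ------------------------------------
## The published layout packages each model's run files into one zip
## archive. Files are stored uncompressed (CSV text, reproducibility over
## size); CRC-32 is computed in C. Timestamps are fixed so archives are
## deterministic.

.zipU16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.zipU32 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

.zipWrite <- function(zipPath, files, names) {
  con <- file(zipPath, open = "wb")
  on.exit(close(con))
  offsets <- numeric(length(files))
  sizes <- numeric(length(files))
  crcs <- numeric(length(files))
  pos <- 0
  for (i in seq_along(files)) {
    data <- readBin(files[i], "raw", n = file.info(files[i])$size)
    nameRaw <- charToRaw(names[i])
    crcs[i] <- cpp_crc32(data)
    sizes[i] <- length(data)
    offsets[i] <- pos
    hdr <- c(
      as.raw(c(0x50, 0x4b, 0x03, 0x04)),
      .zipU16(20), .zipU16(0), .zipU16(0),   # version, flags, method=store
      .zipU16(0), .zipU16(0x21),             # fixed mod time/date
      .zipU32(crcs[i]), .zipU32(sizes[i]), .zipU32(sizes[i]),
      .zipU16(length(nameRaw)), .zipU16(0))
    writeBin(hdr, con)
    writeBin(nameRaw, con)
    writeBin(data, con)
    pos <- pos + length(hdr) + length(nameRaw) + length(data)
  }
  cdStart <- pos
  cdSize <- 0
  for (i in seq_along(files)) {
    nameRaw <- charToRaw(names[i])
    cd <- c(
      as.raw(c(0x50, 0x4b, 0x01, 0x02)),
      .zipU16(20), .zipU16(20), .zipU16(0), .zipU16(0),
      .zipU16(0), .zipU16(0x21),
      .zipU32(crcs[i]), .zipU32(sizes[i]), .zipU32(sizes[i]),
      .zipU16(length(nameRaw)), .zipU16(0), .zipU16(0),
      .zipU16(0), .zipU16(0), .zipU32(0), .zipU32(offsets[i]))
    writeBin(cd, con)
    writeBin(nameRaw, con)
    cdSize <- cdSize + length(cd) + length(nameRaw)
  }
  eocd <- c(as.raw(c(0x50, 0x4b, 0x05, 0x06)),
            .zipU16(0), .zipU16(0),
            .zipU16(length(files)), .zipU16(length(files)),
            .zipU32(cdSize), .zipU32(cdStart), .zipU16(0))
  writeBin(eocd, con)
  invisible(zipPath)
}

#' Package one model's run files into a zip archive
#'
#' Collects the model's CSV run files (and its slice of the manifest, when
#' present) into `<symbol>.zip` next to the model directory, mirroring the
#' published per-model archives. Archives are store-only (uncompressed) and
#' deterministic.
#'
#' @param symbol model symbol.
#' @param dir dataset root directory (as written by [generateDataset()]).
#' @return path of the created archive.
#' @export
packageModel <- function(symbol, dir) {
  modelDir <- file.path(dir, symbol)
  if (!dir.exists(modelDir))
    stop("no directory for model ", symbol, " under ", dir, call. = FALSE)
  files <- sort(list.files(modelDir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files))
    stop("no run files for model ", symbol, " under ", dir, call. = FALSE)
  names <- file.path(symbol, basename(files))
  manPath <- file.path(dir, "manifest.json")
  if (file.exists(manPath)) {
    man <- readManifest(dir)
    slice <- man$runs[man$runs$model == symbol, , drop = FALSE]
    slicePath <- file.path(tempdir(), paste0(symbol, "_manifest.json"))
    jsonlite::write_json(
      lapply(seq_len(nrow(slice)), function(i) list(
        model = slice$model[i], run = slice$run[i], seed = slice$seed[i],
        retries = slice$retries[i], ic = slice$ic[[i]],
        file = file.path(symbol, basename(slice$file[i])))),
      slicePath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, slicePath)
    names <- c(names, file.path(symbol, "manifest.json"))
  }
  zipPath <- file.path(dir, paste0(symbol, ".zip"))
  .zipWrite(zipPath, files, names)
  zipPath
}

setMethod("show", "RunFile", function(object) {
  cat(sprintf("RunFile %s (%s run %d): %d x %d\n", basename(object@path),
              object@modelSymbol, object@runIndex, nrow(object@values),
              ncol(object@values)))
})
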