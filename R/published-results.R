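## Published confusion-matrix rows of the three validation experiments, as
## printed: experiment 1 (whole-signal segments), experiment 2 (first
## segments), experiment 3 evaluated on the quasi-periodic-augmented test
## sets in both whole-signal and first-segment variants.

#' Published benchmark results
#'
#' The confusion-matrix rows (accuracy, TP, FN, TN, FP; chaos positive)
#' reported for the original full-size benchmark, one row per (experiment,
#' segmentation variant, architecture, segment length). Useful as the
#' reference the package's experiments are compared against, and for
#' checking accuracy/count consistency. Note that a few published accuracy
#' values are truncated rather than rounded to 3 decimals, and one row's
#' positive counts differ slightly from the nominal test-set composition;
#' the counts are reproduced verbatim.
#'
#' @return data.frame with columns `experiment`, `variant`
#'   (`"whole"`/`"first"`), `arch`, `segment`, `accuracy`, `tp`, `fn`,
#'   `tn`, `fp`.
#' @export
publishedResults <- function() {
  rows <- rbind(
    ## experiment 1, whole signals
    c(1, "whole", "lstm",  50, 0.978, 107389, 5651, 139992,     8),
    c(1, "whole", "lstm", 100, 0.989,  55233, 1287,  70000,     0),
    c(1, "whole", "lstm", 200, 0.991,  27708,  552,  35000,     0),
    c(1, "whole", "cnn",   50, 0.979, 108195, 4845, 139757,   243),
    c(1, "whole", "cnn",  100, 0.982,  54781, 1713,  69457,   543),
    c(1, "whole", "cnn",  200, 0.985,  27360,  900,  34982,    18),
    ## experiment 2, first segments
    c(2, "first", "lstm",  50, 0.982,   5485,  167,   6942,    58),
    c(2, "first", "lstm", 100, 0.977,   5357,  295,   7000,     0),
    c(2, "first", "lstm", 200, 0.981,   5419,  233,   7000,     0),
    c(2, "first", "cnn",   50, 0.980,   5650,    2,   6744,   256),
    c(2, "first", "cnn",  100, 0.979,   5499,  153,   6885,   115),
    c(2, "first", "cnn",  200, 0.980,   5397,  255,   7000,     0),
    ## experiment 3, whole signals, QPS-augmented test set
    c(3, "whole", "lstm",  50, 0.967, 107389, 5651, 195423,  4637),
    c(3, "whole", "lstm", 100, 0.985,  55233, 1287,  99022,  1008),
    c(3, "whole", "lstm", 200, 0.984,  27708,  552,  49352,   663),
    c(3, "whole", "cnn",   50, 0.924, 108288, 4752, 180873, 19187),
    c(3, "whole", "cnn",  100, 0.902,  54781, 1739,  86382, 13648),
    c(3, "whole", "cnn",  200, 0.957,  27360,  900,  47584,  2431),
    ## experiment 3, first segments, QPS-augmented test set
    c(3, "first", "lstm",  50, 0.937,   5485,  167,   9183,   817),
    c(3, "first", "lstm", 100, 0.981,   5357,  295,  10000,     0),
    c(3, "first", "lstm", 200, 0.952,   5419,  233,   9488,   512),
    c(3, "first", "cnn",   50, 0.951,   5650,    2,   9235,   765),
    c(3, "first", "cnn",  100, 0.943,   5499,  153,   9262,   738),
    c(3, "first", "cnn",  200, 0.970,   5397,  255,   9785,   215)
  )
  out <- data.frame(
    experiment = as.integer(rows[, 1]),
    variant = rows[, 2],
    arch = rows[, 3],
    segment = as.integer(rows[, 4]),
    accuracy = as.numeric(rows[, 5]),
    tp = as.numeric(rows[, 6]), fn = as.numeric(rows[, 7]),
    tn = as.numeric(rows[, 8]), fp = as.numeric(rows[, 9]),
    stringsAsFactors = FALSE)
  out
}
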