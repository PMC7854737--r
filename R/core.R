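# Recursive dynamic functional connectivity: sliding-window Pearson
# correlation applied recursively to a triplet's signals.
#
# Pairing convention (fixed throughout the package): for an ordered sequence
# (e1, e2, e3), coordinate x holds corr(e1, e2), y holds corr(e1, e3) and z
# holds corr(e2, e3). The same rule is applied to the three series at every
# order, with the series ordered (x-pair, y-pair, z-pair). The convention is
# arbitrary but must stay fixed so that permuting the electrode sequence
# permutes pattern coordinates lawfully.

PAIRS <- rbind(x = c(1L, 2L), y = c(1L, 3L), z = c(2L, 3L))

#' Sliding-window Pearson correlation
#'
#' Correlation of two equal-length signals in a window of `window` samples
#' moved along by `step` samples (default 1, the method's convention). Entry
#' t is the Pearson correlation of the two windows starting at sample
#' (t-1)*step + 1. Windows where either signal is constant cannot define a
#' correlation; they contribute the degenerate value 0 and are counted in the
#' `n_degenerate` attribute rather than poisoning higher orders with NaN.
#'
#' @param a,b numeric signals of equal length >= `window`.
#' @param window window length in samples (>= 2).
#' @param step slide in samples (default 1).
#' @return Numeric vector of length `floor((length(a) - window)/step) + 1`,
#'   values in [-1, 1], with attribute `n_degenerate`.
#' @export
sliding_correlation <- function(a, b, window, step = 1L) {
  if (length(a) != length(b))
    abort_rdfc("signals must have equal length", "rdfc_length_error")
  if (window > length(a))
    abort_rdfc("window exceeds signal length", "rdfc_length_error")
  if (window < 2L) abort_rdfc("window must be >= 2 samples", "rdfc_param_error")
  roll_corr_cpp(as.numeric(a), as.numeric(b), as.integer(window),
                as.integer(step))
}

#' One recursion step: trivariate dynamic connectivity series
#'
#' Applies [sliding_correlation()] to the three pairs of an ordered triple of
#' signals, producing the next-order dynamic functional connectivity
#' time-series. Rows follow the pairing convention: x from (1,2), y from
#' (1,3), z from (2,3).
#'
#' @param tri 3 x N numeric matrix (ordered signals as rows).
#' @param window window length in samples.
#' @param step slide in samples (default 1).
#' @return A `dfc_series`: list with `series` (3 x L matrix, rows x/y/z),
#'   `window`, `source_length` and `n_degenerate`.
#' @export
dfc_step <- function(tri, window, step = 1L) {
  tri <- as.matrix(tri)
  if (nrow(tri) != 3L) abort_rdfc("dfc_step needs exactly 3 signals", "rdfc_value_error")
  rows <- lapply(seq_len(3L), function(k)
    sliding_correlation(tri[PAIRS[k, 1L], ], tri[PAIRS[k, 2L], ], window, step))
  series <- do.call(rbind, lapply(rows, as.numeric))
  rownames(series) <- c("x", "y", "z")
  structure(list(series = series, window = as.integer(window),
                 source_length = ncol(tri),
                 n_degenerate = sum(vapply(rows, attr, 0L, "n_degenerate"))),
            class = "dfc_series")
}

#' Static connectivity summary of a trivariate series
#'
#' The three full-length pairwise Pearson coefficients of an ordered triple
#' of signals, in pairing-convention order (x, y, z). A constant series pairs
#' to the degenerate value 0.
#'
#' @param tri 3 x N numeric matrix.
#' @return Named numeric vector `c(x=, y=, z=)` in [-1, 1].
#' @export
static_summary <- function(tri) {
  tri <- as.matrix(tri)
  if (nrow(tri) != 3L) abort_rdfc("static_summary needs exactly 3 signals", "rdfc_value_error")
  if (ncol(tri) < 2L) abort_rdfc("signals must have length >= 2", "rdfc_length_error")
  sds <- apply(tri, 1L, sd)
  out <- vapply(seq_len(3L), function(k) {
    i <- PAIRS[k, 1L]; j <- PAIRS[k, 2L]
    if (sds[i] == 0 || sds[j] == 0) 0 else cor(tri[i, ], tri[j, ])
  }, 0)
  names(out) <- c("x", "y", "z")
  pmin(1, pmax(-1, out))
}

#' Compute the rdFC pattern of a triplet sequence
#'
#' Runs the full recursion on one epoch: order 1 is the static summary of the
#' three (already filtered) signals; each further order slides a
#' `window`-second Pearson window over the previous order's trivariate series
#' and summarises it statically. The default five orders give the 5-point
#' pattern; the recursion depth is configurable (beyond five the points
#' shrink toward the origin and carry little discriminative structure).
#'
#' The window is specified in seconds and converted to samples as
#' `round(window * rate)`, so the method transfers across sampling rates; the
#' same sample count is reused at every order.
#'
#' @param epoch an [eeg_epoch()] containing the three channels.
#' @param seq a [triplet_sequence()] (or character vector of 3 labels).
#' @param window window length in seconds (default 1).
#' @param orders number of connectivity orders (default 5).
#' @param step slide in samples (default 1).
#' @return An [rdfc_pattern()] with `orders` rows.
#' @export
compute_pattern <- function(epoch, seq, window = 1, orders = 5L, step = 1L) {
  if (is.character(seq)) seq <- triplet_sequence(seq)
  missing_ch <- setdiff(seq$labels, epoch$labels)
  if (length(missing_ch))
    abort_rdfc(paste0("channel(s) not in epoch: ", paste(missing_ch, collapse = ", ")),
               "rdfc_channel_error")
  w <- as.integer(round(window * epoch$rate))
  tri <- epoch$samples[seq$labels, , drop = FALSE]
  if (ncol(tri) < (orders - 1L) * (w - 1L) * step + 2L)
    abort_rdfc("epoch too short for the requested window and order count",
               "rdfc_length_error")
  points <- matrix(NA_real_, nrow = orders, ncol = 3L)
  points[1L, ] <- static_summary(tri)
  series <- tri
  for (n in seq_len(orders - 1L)) {
    series <- dfc_step(series, w, step)$series
    points[n + 1L, ] <- static_summary(series)
  }
  rdfc_pattern(points, labels = seq$labels, permutation_id = seq$permutation_id,
               start_time = epoch$start_time, window = w, rate = epoch$rate)
}

# the six orderings of positions (1,2,3), lexicographic; id 1 = identity
PERMS3 <- rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))

#' Enumerate the six permutations of a triplet
#'
#' An unordered triplet can be arranged in P(3,3) = 6 sequences; each fixes a
#' different coordinate assignment and hence its own rdFC pattern.
#' Permutations are indexed 1..6 lexicographically over the input order, with
#' id 1 the identity.
#'
#' @param triplet character vector of 3 distinct labels.
#' @return List of 6 [triplet_sequence()] objects.
#' @export
enumerate_permutations <- function(triplet) {
  triplet <- as.character(triplet)
  if (length(triplet) != 3L || anyDuplicated(triplet))
    abort_rdfc("a triplet needs 3 distinct labels", "rdfc_value_error")
  lapply(seq_len(6L), function(i)
    triplet_sequence(triplet[PERMS3[i, ]], permutation_id = i))
}

#' Count static measures of the recursion for k starting nodes
#'
#' With `start_nodes` nodes the first order yields C(n, 2) pairwise measures;
#' each further order pairs the previous order's series among themselves,
#' c(next) = C(c, 2). Three starting nodes keep the count fixed at 3 per
#' order; four nodes already explode past 1.49e7 measures over five orders,
#' which is why the method uses triplets.
#'
#' @param start_nodes number of starting nodes (>= 2).
#' @param orders recursion depth (>= 1).
#' @return Total number of static measures over all orders (numeric; counts
#'   can exceed integer range).
#' @export
count_static_measures <- function(start_nodes, orders) {
  stopifnot(start_nodes >= 2, orders >= 1)
  c_n <- choose(start_nodes, 2)
  total <- c_n
  for (n in seq_len(orders - 1L)) {
    c_n <- choose(c_n, 2)
    total <- total + c_n
  }
  total
}

# ---- pattern serialization ------------------------------------------------

pattern_row <- function(p) {
  pts <- as.vector(t(p$points))
  names(pts) <- paste0(rep(c("x", "y", "z"), nrow(p$points)),
                       rep(seq_len(nrow(p$points)), each = 3L))
  data.frame(triplet = paste(if (is.null(p$labels)) c("?", "?", "?") else p$labels,
                             collapse = ","),
             permutation_id = p$permutation_id, start_time = p$start_time,
             window = p$window, rate = p$rate, t(pts),
             stringsAsFactors = FALSE)
}

#' Write / read rdFC patterns
#'
#' Patterns serialize to a tab-separated table (one row per pattern: triplet,
#' permutation id, epoch start, window, rate, then the coordinates x1..z5) or
#' to JSON with the same content; both round-trip losslessly at full double
#' precision.
#'
#' @param patterns an [rdfc_pattern()] or list of them.
#' @param path output file path.
#' @param format `"tsv"` or `"json"`; guessed from the extension on read.
#' @return `write_patterns` returns `path` invisibly; `read_patterns` returns
#'   a list of [rdfc_pattern()] objects.
#' @export
write_patterns <- function(patterns, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (inherits(patterns, "rdfc_pattern")) patterns <- list(patterns)
  df <- do.call(rbind, lapply(patterns, pattern_row))
  if (format == "json") {
    jsonlite::write_json(df, path, digits = NA, dataframe = "rows")
  } else {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  df <- if (format == "json") as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
        else read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  coord_cols <- grep("^[xyz][0-9]+$", names(df), value = TRUE)
  orders <- length(coord_cols) / 3L
  lapply(seq_len(nrow(df)), function(i) {
    pts <- matrix(as.numeric(df[i, paste0(rep(c("x", "y", "z"), orders),
                                          rep(seq_len(orders), each = 3L))]),
                  ncol = 3L, byrow = TRUE)
    rdfc_pattern(pts, labels = strsplit(df$triplet[i], ",")[[1L]],
                 permutation_id = df$permutation_id[i],
                 start_time = df$start_time[i], window = df$window[i],
                 rate = df$rate[i])
  })
}
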