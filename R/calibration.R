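# Monte-Carlo calibration of the significance threshold and the statistics
# built on matches: match vectors over permutations, prevalence, prediction
# accuracy from the first-order point, and the Mann-Whitney gap comparison.

#' Generate random pseudo-patterns
#'
#' A pseudo-pattern is a random 5-point pattern: 15 values drawn iid
#' Uniform(-1, 1), three per order. An ensemble of these provides the null
#' distribution of match scores for threshold calibration.
#'
#' @param n number of patterns.
#' @param seed RNG seed (recorded; the global RNG state is untouched).
#' @param orders number of orders per pattern (default 5).
#' @return n x (3*orders) numeric matrix; each row is one pattern, columns
#'   x1, y1, z1, x2, ...
#' @export
generate_pseudo_patterns <- function(n, seed, orders = 5L) {
  stopifnot(n >= 1)
  m <- withr::with_seed(seed, matrix(runif(n * 3L * orders, -1, 1), nrow = n))
  colnames(m) <- paste0(rep(c("x", "y", "z"), orders),
                        rep(seq_len(orders), each = 3L))
  m
}

# normalized segment directions of row-wise flattened patterns (n x 3k),
# returned as n x 3(k-1); zero-length segments become zero rows
flat_segment_directions <- function(m) {
  orders <- ncol(m) / 3L
  out <- matrix(0, nrow = nrow(m), ncol = 3L * (orders - 1L))
  for (i in seq_len(orders - 1L)) {
    d <- m[, (3L * i + 1L):(3L * i + 3L), drop = FALSE] -
         m[, (3L * i - 2L):(3L * i), drop = FALSE]
    nrm <- sqrt(rowSums(d^2))
    ok <- nrm > 1e-12
    d[ok, ] <- d[ok, , drop = FALSE] / nrm[ok]
    d[!ok, ] <- 0
    out[, (3L * i - 2L):(3L * i)] <- d
  }
  out
}

# best-of-three match scores of flattened patterns against a reference set
null_best_scores <- function(m, refs) {
  a <- flat_segment_directions(m)
  scores <- vapply(refs$patterns, function(r) {
    b <- as.vector(t(segment_directions(r)))
    as.vector(a %*% b)
  }, numeric(nrow(m)))
  do.call(pmax, as.data.frame(scores))
}

#' Calibrate the significance threshold by Monte Carlo
#'
#' Matches `n` random pseudo-patterns (best of the three references each)
#' and returns the requested percentile of the null best scores as the
#' significance cutoff: by construction, only (100 - percentile)% of random
#' patterns reach it. With the standard 100,000 patterns and the 95th
#' percentile against a permutation-related reference triple the cutoff
#' lands near 2.65. The threshold depends on the reference geometry and is
#' therefore reported per reference set.
#'
#' @param refs a [reference_set()].
#' @param n number of pseudo-patterns (default 1e5).
#' @param percentile percentile of the null distribution (default 95).
#' @param seed RNG seed.
#' @param keep_scores retain the null scores in the result (default FALSE).
#' @return A `threshold_calibration`: list with `threshold`, `n_patterns`,
#'   `percentile`, `seed` and optionally `score_sample`.
#' @export
calibrate_threshold <- function(refs, n = 100000L, percentile = 95,
                                seed = 1L, keep_scores = FALSE) {
  stopifnot(n >= 1)
  dirs <- lapply(refs$patterns, segment_directions)
  if (all(vapply(dirs, function(d) all(attr(d, "null")), TRUE)))
    abort_rdfc("degenerate reference set: all segments have zero length",
               "rdfc_calibration_error")
  best <- null_best_scores(generate_pseudo_patterns(n, seed), refs)
  structure(list(threshold = unname(quantile(best, percentile / 100, type = 7)),
                 n_patterns = as.integer(n), percentile = percentile,
                 seed = as.integer(seed),
                 score_sample = if (keep_scores) best else NULL),
            class = "threshold_calibration")
}

#' Match vector of a triplet over its six permutations
#'
#' Computes the rdFC pattern of each of the six permutations of an unordered
#' triplet on one epoch, matches each against the reference set, and counts
#' how many significant patterns fall to each reference. Entries lie in 0..6
#' and sum to the number of significant permutations (at most 6).
#'
#' @param triplet character vector of 3 distinct labels.
#' @param epoch an [eeg_epoch()] containing the channels.
#' @param refs a [reference_set()].
#' @param threshold significance cutoff.
#' @param window window length in seconds.
#' @param orders recursion depth.
#' @return A `match_vector`: list with `counts` (3), `triplet`,
#'   `n_significant` and per-permutation `results`.
#' @export
match_vector <- function(triplet, epoch, refs, threshold = 2.65, window = 1,
                         orders = 5L) {
  perms <- enumerate_permutations(triplet)
  results <- lapply(perms, function(sq)
    best_match(compute_pattern(epoch, sq, window = window, orders = orders),
               refs, threshold))
  sig <- vapply(results, `[[`, TRUE, "significant")
  ids <- vapply(results, `[[`, 0L, "best_id")
  counts <- tabulate(ids[sig], nbins = 3L)
  structure(list(counts = counts, triplet = as.character(triplet),
                 n_significant = sum(sig), results = results),
            class = "match_vector")
}

#' @export
print.match_vector <- function(x, ...) {
  cat(sprintf("<match_vector> (%s): [%s], %d/6 significant\n",
              paste(x$triplet, collapse = ","),
              paste(x$counts, collapse = " "), x$n_significant))
  invisible(x)
}

#' Prevalence summary of match results
#'
#' For a collection of `match_result`s: the percentage frequency with which
#' each reference is the best match among significant patterns, and the
#' overall match percentage (significant / all). For a collection of
#' `match_vector`s: additionally the histogram of match-vector entries
#' (0..6 permutations per reference).
#'
#' @param results nonempty list of `match_result` and/or `match_vector`
#'   objects.
#' @return List with `frequencies_pct` (named, sums to 100 over matched
#'   patterns), `overall_match_pct`, `n_patterns`, `n_matched` and, when
#'   match vectors are present, `entry_histogram` (counts of 0..6).
#' @export
prevalence_summary <- function(results) {
  if (!length(results)) abort_rdfc("empty result collection", "rdfc_value_error")
  mv <- Filter(function(x) inherits(x, "match_vector"), results)
  mr <- Filter(function(x) inherits(x, "match_result"), results)
  mr <- c(mr, unlist(lapply(mv, `[[`, "results"), recursive = FALSE))
  if (!length(mr)) abort_rdfc("no match results in collection", "rdfc_value_error")
  sig <- vapply(mr, `[[`, TRUE, "significant")
  ids <- vapply(mr, `[[`, 0L, "best_id")
  counts <- tabulate(ids[sig], nbins = 3L)
  freq <- if (sum(counts) > 0) 100 * counts / sum(counts) else rep(NA_real_, 3L)
  names(freq) <- paste0("reference", 1:3)
  out <- list(frequencies_pct = freq,
              overall_match_pct = 100 * mean(sig),
              n_patterns = length(mr), n_matched = sum(sig))
  if (length(mv)) {
    entries <- unlist(lapply(mv, `[[`, "counts"))
    out$entry_histogram <- tabulate(entries + 1L, nbins = 7L)
    names(out$entry_histogram) <- as.character(0:6)
  }
  out
}

#' Prediction accuracy from the first-order point
#'
#' Restricts to patterns matching exactly one reference (exclusive matches;
#' their share is reported as the exclusivity rate), predicts the reference
#' from the lowest first-order coordinate via [predict_reference()], and
#' returns the percentage agreeing with the actual best match. Ambiguous
#' first-order ties are excluded from the denominator.
#'
#' @param patterns list of [rdfc_pattern()] objects.
#' @param refs a [reference_set()].
#' @param threshold significance cutoff.
#' @param mapping coordinate-to-reference table; defaults to the set's own.
#' @return List with `accuracy_pct` (`NA` when no exclusive matches),
#'   `n_exclusive`, `n_matched`, `exclusivity_rate_pct` and `n_ambiguous`.
#' @export
prediction_accuracy <- function(patterns, refs, threshold = 2.65,
                                mapping = refs$mapping) {
  if (!length(patterns)) abort_rdfc("empty pattern collection", "rdfc_value_error")
  res <- lapply(patterns, best_match, refs = refs, threshold = threshold)
  sig <- vapply(res, `[[`, TRUE, "significant")
  excl <- vapply(res, `[[`, TRUE, "exclusive") & sig
  preds <- lapply(patterns[excl], predict_reference, mapping = mapping)
  amb <- vapply(preds, `[[`, TRUE, "ambiguous")
  hits <- mapply(function(p, r) identical(p$reference, r$best_id),
                 preds[!amb], res[excl][!amb])
  list(accuracy_pct = if (length(hits)) 100 * mean(hits) else NA_real_,
       n_exclusive = sum(excl), n_matched = sum(sig),
       exclusivity_rate_pct = if (sum(sig)) 100 * sum(excl) / sum(sig) else NA_real_,
       n_ambiguous = sum(amb))
}

#' Mann-Whitney comparison of coordinate gaps
#'
#' Two-sided Mann-Whitney U test between the first-order coordinate gaps of
#' exclusively matching patterns and double-matching patterns. The common
#' language effect size, which equals the area under the ROC curve, is
#' U/(n1 n2) with U the larger of the two statistics. Medians and
#' interquartile ranges are reported directly; no Fisher transformation is
#' applied since the rank test does not require Gaussian samples. Small
#' samples (both groups <= 20, no ties) use the exact distribution;
#' otherwise the tie-corrected normal approximation.
#'
#' @param group_exclusive,group_double numeric gap values of the two groups.
#' @return A `gap_test_result`: list with `U` (larger statistic), `p`,
#'   `cles`, `median1`, `median2`, `iqr1`, `iqr2`, `n1`, `n2`.
#' @export
gap_test <- function(group_exclusive, group_double) {
  n1 <- length(group_exclusive); n2 <- length(group_double)
  if (n1 == 0 || n2 == 0) abort_rdfc("both groups must be nonempty", "rdfc_value_error")
  ties <- anyDuplicated(c(group_exclusive, group_double)) > 0
  exact <- n1 <= 20 && n2 <= 20 && !ties
  wt <- suppressWarnings(wilcox.test(group_exclusive, group_double,
                                     alternative = "two.sided", exact = exact,
                                     correct = TRUE))
  u1 <- unname(wt$statistic)            # U of the first sample
  u_larger <- max(u1, n1 * n2 - u1)
  structure(list(U = u_larger, p = wt$p.value, cles = u_larger / (n1 * n2),
                 median1 = median(group_exclusive), median2 = median(group_double),
                 iqr1 = IQR(group_exclusive), iqr2 = IQR(group_double),
                 n1 = n1, n2 = n2),
            class = "gap_test_result")
}

#' @export
print.gap_test_result <- function(x, ...) {
  cat(sprintf("<gap_test> U = %g, p = %.3g, CLES = %.3f; medians %.4f vs %.4f (n = %d, %d)\n",
              x$U, x$p, x$cles, x$median1, x$median2, x$n1, x$n2))
  invisible(x)
}
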