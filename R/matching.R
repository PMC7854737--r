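# Pattern matching: scale- and translation-invariant comparison of 5-point
# patterns via the directions of their four connecting segments. Two patterns
# with the same segment directions have the same shape regardless of the
# absolute correlation strengths (size) or their location in correlation
# space, which is exactly the invariance the correlation structure calls for.

#' Normalized segment directions of a pattern
#'
#' The unit vectors along the four segments joining consecutive points of the
#' pattern. A zero-length segment (coincident points) has no direction: it is
#' returned as a zero row and flagged, and contributes nothing to a match
#' score, so degenerate patterns score low instead of erroring.
#'
#' @param p an [rdfc_pattern()] with at least 2 rows.
#' @return (orders-1) x 3 matrix of unit (or flagged zero) rows, with logical
#'   attribute `null` marking degenerate segments.
#' @export
segment_directions <- function(p) {
  pts <- p$points
  if (nrow(pts) < 2L) abort_rdfc("pattern needs >= 2 points", "rdfc_shape_error")
  d <- diff(pts)
  nrm <- sqrt(rowSums(d^2))
  null <- nrm <= 1e-12 * max(1, max(abs(pts)))
  d[null, ] <- 0
  d[!null, ] <- d[!null, , drop = FALSE] / nrm[!null]
  attr(d, "null") <- null
  d
}

#' Match score between two rdFC patterns
#'
#' Sum of the dot products of the four normalized segment directions of the
#' two patterns: `sum_i <a_i, b_i>`, ranging from -4 (mirror-reversed shape)
#' to +4 (identical shape). The score depends only on segment directions, so
#' it is invariant to positive rescaling and translation of either pattern.
#'
#' @param sample,reference [rdfc_pattern()] objects with equal row counts.
#' @return Scalar score in [-4, 4].
#' @export
match_score <- function(sample, reference) {
  if (nrow(sample$points) != nrow(reference$points))
    abort_rdfc("patterns must have equal row counts", "rdfc_shape_error")
  a <- segment_directions(sample)
  b <- segment_directions(reference)
  sum(rowSums(a * b))
}

#' Match a pattern against a reference set
#'
#' Scores the sample against all three references; the highest of the three
#' is the pattern's match score. The match is significant when the best score
#' reaches `threshold` (the Monte-Carlo calibrated cutoff, 2.65 by default),
#' and exclusive when exactly one reference reaches it. Score ties break to
#' the lowest reference index.
#'
#' @param sample an [rdfc_pattern()].
#' @param refs a [reference_set()].
#' @param threshold significance cutoff on the score (see
#'   [calibrate_threshold()]).
#' @return A `match_result`: list with `scores` (3), `best_id`, `best_score`,
#'   `significant`, `exclusive` and the `threshold` used.
#' @export
best_match <- function(sample, refs, threshold = 2.65) {
  scores <- vapply(refs$patterns, function(r) match_score(sample, r), 0)
  best_id <- which.max(scores)            # which.max ties -> lowest index
  structure(list(scores = scores, best_id = best_id,
                 best_score = scores[best_id],
                 significant = scores[best_id] >= threshold,
                 exclusive = sum(scores >= threshold) == 1L,
                 threshold = threshold),
            class = "match_result")
}

#' Predict the matching reference from the first-order point
#'
#' The reference a pattern matches is strongly determined by which coordinate
#' carries the lowest first-order correlation: with the default mapping,
#' lowest at x predicts reference 3, at y reference 2, at z reference 1. No
#' information from orders 2-5 is used. An exact tie between the two smallest
#' coordinates is reported as ambiguous with both candidate references.
#'
#' @param sample an [rdfc_pattern()].
#' @param mapping named vector `c(x=, y=, z=)` of reference indices; defaults
#'   to the mapping stored in a [reference_set()] built by
#'   [generate_reference_set()].
#' @return List with `reference` (index, `NA` when ambiguous), `coordinate`,
#'   `ambiguous` and `candidates`.
#' @export
predict_reference <- function(sample, mapping = c(x = 3L, y = 2L, z = 1L)) {
  p1 <- sample$points[1L, ]
  ord <- order(p1)
  ambiguous <- (p1[ord[2L]] - p1[ord[1L]]) <= 1e-12
  coords <- c("x", "y", "z")
  if (ambiguous) {
    cand <- unname(mapping[coords[ord[1:2]]])
    list(reference = NA_integer_, coordinate = NA_character_,
         ambiguous = TRUE, candidates = as.integer(cand))
  } else {
    list(reference = as.integer(mapping[coords[ord[1L]]]),
         coordinate = coords[ord[1L]], ambiguous = FALSE,
         candidates = as.integer(mapping[coords[ord[1L]]]))
  }
}

#' Gap between the two smallest first-order coordinates
#'
#' Difference between the second-smallest and smallest of the first-order
#' coordinates (x1, y1, z1). A small gap means two candidate references score
#' highly at once (double matches); the gap distributions of exclusive versus
#' double matches are compared with [gap_test()].
#'
#' @param sample an [rdfc_pattern()].
#' @return Nonnegative scalar.
#' @export
coordinate_gap <- function(sample) {
  p1 <- sort(sample$points[1L, ])
  unname(p1[2L] - p1[1L])
}

#' Write / read a reference set
#'
#' Reference sets use the pattern JSON layout plus the coordinate mapping and
#' provenance, and round-trip losslessly.
#'
#' @param refs a [reference_set()].
#' @param path output file path (JSON).
#' @return `write_reference_set` returns `path` invisibly;
#'   `read_reference_set` returns a [reference_set()].
#' @export
write_reference_set <- function(refs, path) {
  obj <- list(mapping = as.list(refs$mapping), provenance = refs$provenance,
              patterns = lapply(refs$patterns, function(p)
                list(points = p$points, labels = p$labels,
                     permutation_id = p$permutation_id,
                     start_time = p$start_time, window = p$window,
                     rate = p$rate)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_reference_set
#' @export
read_reference_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pats <- lapply(seq_len(length(obj$patterns$permutation_id)), function(i)
    rdfc_pattern(obj$patterns$points[[i]],
                 labels = obj$patterns$labels[[i]],
                 permutation_id = obj$patterns$permutation_id[i],
                 start_time = obj$patterns$start_time[i],
                 window = obj$patterns$window[i],
                 rate = obj$patterns$rate[i]))
  reference_set(pats, mapping = unlist(obj$mapping), provenance = obj$provenance)
}
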