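#' Multichannel EEG record
#'
#' Container for a multichannel EEG signal together with its sampling rate,
#' channel labels (10--20 system), reference scheme and optional annotations.
#' This is the raw input object on which preprocessing operates.
#'
#' @param samples numeric matrix, channels x time, in microvolts. Row names,
#'   if present, must agree with `labels`.
#' @param rate sampling frequency in Hz; must be positive.
#' @param labels character vector of unique channel names, one per row of
#'   `samples`.
#' @param reference reference-scheme tag: a named electrode (e.g. `"T3"`),
#'   `"average"`, `"bipolar"`, or `"unknown"`.
#' @param annotations optional data frame with columns `onset` (seconds from
#'   record start) and `label`, e.g. seizure-onset marks.
#'
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(samples, rate, labels = rownames(samples),
                       reference = "unknown", annotations = NULL) {
  samples <- as.matrix(samples)
  if (is.null(labels)) abort_rdfc("channel labels are required", "rdfc_metadata_error")
  labels <- as.character(labels)
  if (length(labels) != nrow(samples))
    abort_rdfc("one label per channel is required", "rdfc_metadata_error")
  if (anyDuplicated(labels)) abort_rdfc("channel labels must be unique", "rdfc_metadata_error")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    abort_rdfc("sampling rate must be a positive scalar", "rdfc_param_error")
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    stopifnot(all(c("onset", "label") %in% names(annotations)))
  }
  rownames(samples) <- labels
  structure(list(samples = samples, rate = rate, labels = labels,
                 reference = reference, annotations = annotations),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d channels x %d samples @ %g Hz (%.1f s), reference: %s\n",
              nrow(x$samples), ncol(x$samples), x$rate,
              ncol(x$samples) / x$rate, x$reference))
  cat("  channels:", paste(utils::head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) "..." else "", "\n")
  if (!is.null(x$annotations))
    cat(sprintf("  annotations: %d events\n", nrow(x$annotations)))
  invisible(x)
}

#' Analysis epoch extracted from an EEG record
#'
#' A fixed-duration window of an [eeg_record()], by default the 5-minute
#' (300 s) analysis epoch on which rdFC patterns are computed.
#'
#' @param samples numeric matrix, channels x time.
#' @param rate sampling frequency in Hz.
#' @param labels channel names.
#' @param start_time offset of the epoch start into the source record (s).
#' @param duration epoch duration (s); must agree with the sample count to
#'   within one sample.
#' @param substituted `TRUE` when the requested epoch was flat-lined and a
#'   later epoch was used instead.
#'
#' @return An object of class `eeg_epoch`.
#' @export
eeg_epoch <- function(samples, rate, labels = rownames(samples),
                      start_time = 0, duration = ncol(samples) / rate,
                      substituted = FALSE) {
  samples <- as.matrix(samples)
  labels <- as.character(labels)
  if (abs(duration * rate - ncol(samples)) > 1)
    abort_rdfc("duration, rate and sample count disagree", "rdfc_length_error")
  rownames(samples) <- labels
  structure(list(samples = samples, rate = rate, labels = labels,
                 start_time = start_time, duration = duration,
                 substituted = substituted),
            class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> %d channels x %d samples @ %g Hz, [%g s, %g s)%s\n",
              nrow(x$samples), ncol(x$samples), x$rate, x$start_time,
              x$start_time + x$duration,
              if (isTRUE(x$substituted)) " (substituted)" else ""))
  invisible(x)
}

#' Ordered electrode triplet sequence
#'
#' An ordered arrangement of three distinct electrode labels. The order fixes
#' the coordinate assignment of the pairwise correlations: for sequence
#' (e1, e2, e3), x is corr(e1, e2), y is corr(e1, e3) and z is corr(e2, e3),
#' at every order of the recursion.
#'
#' @param labels character vector of 3 distinct channel names.
#' @param permutation_id integer 1..6 identifying the arrangement relative to
#'   a canonical (sorted or as-given) label order; 1 is the identity.
#'
#' @return An object of class `triplet_sequence`.
#' @seealso [enumerate_permutations()]
#' @export
triplet_sequence <- function(labels, permutation_id = 1L) {
  labels <- as.character(labels)
  if (length(labels) != 3L || anyDuplicated(labels))
    abort_rdfc("a triplet sequence needs 3 distinct labels", "rdfc_value_error")
  structure(list(labels = labels, permutation_id = as.integer(permutation_id)),
            class = "triplet_sequence")
}

#' @export
print.triplet_sequence <- function(x, ...) {
  cat(sprintf("<triplet_sequence> (%s), permutation %d\n",
              paste(x$labels, collapse = ","), x$permutation_id))
  invisible(x)
}

#' Recursive dynamic functional connectivity pattern
#'
#' The central object: one point per connectivity order, each point holding
#' the three pairwise static Pearson correlations (x, y, z) of that order.
#' With the default five orders this is a 5 x 3 matrix of values in [-1, 1],
#' drawn as a 5-point polyline in 3D correlation space.
#'
#' @param points numeric matrix, orders x 3, all entries in [-1, 1].
#' @param labels triplet channel labels (length 3) or `NULL`.
#' @param permutation_id permutation index 1..6, or `NA`.
#' @param start_time epoch start time (s) the pattern was computed from.
#' @param window sliding-window length in samples.
#' @param rate sampling rate (Hz) of the source epoch.
#'
#' @return An object of class `rdfc_pattern`.
#' @export
rdfc_pattern <- function(points, labels = NULL, permutation_id = NA_integer_,
                         start_time = NA_real_, window = NA_integer_,
                         rate = NA_real_) {
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    abort_rdfc("pattern points must have 3 coordinates", "rdfc_value_error")
  if (any(!is.finite(points)) || any(abs(points) > 1 + 1e-9))
    abort_rdfc("pattern coordinates must be finite correlations in [-1, 1]",
               "rdfc_value_error")
  points[] <- pmin(1, pmax(-1, points))
  colnames(points) <- c("x", "y", "z")
  rownames(points) <- paste0("order", seq_len(nrow(points)))
  structure(list(points = points, labels = labels,
                 permutation_id = as.integer(permutation_id),
                 start_time = start_time, window = window, rate = rate),
            class = "rdfc_pattern")
}

#' @export
print.rdfc_pattern <- function(x, digits = 3, ...) {
  cat(sprintf("<rdfc_pattern> %d orders%s%s\n", nrow(x$points),
              if (!is.null(x$labels)) paste0(", triplet (", paste(x$labels, collapse = ","), ")") else "",
              if (!is.na(x$permutation_id)) paste0(", permutation ", x$permutation_id) else ""))
  print(round(x$points, digits))
  invisible(x)
}

#' Reference pattern set
#'
#' Three rdFC patterns related by per-order coordinate permutations,
#' representing one underlying correlation structure; samples are matched
#' against all three. The lowest-coordinate-to-reference mapping used by
#' [predict_reference()] travels with the set because it is only meaningful
#' relative to the pairing convention under which the references were built.
#'
#' @param patterns list of 3 [rdfc_pattern()] objects with equal row counts.
#' @param mapping named integer vector `c(x = , y = , z = )` giving, for each
#'   coordinate, the reference matched when the first-order minimum lies on
#'   that coordinate. Default `c(x = 3, y = 2, z = 1)`.
#' @param provenance free-text description of how the set was built (seed,
#'   epoch metadata, ...).
#'
#' @return An object of class `reference_set`.
#' @export
reference_set <- function(patterns, mapping = c(x = 3L, y = 2L, z = 1L),
                          provenance = "") {
  if (length(patterns) != 3L || !all(vapply(patterns, inherits, TRUE, "rdfc_pattern")))
    abort_rdfc("a reference set holds exactly 3 rdfc_pattern objects", "rdfc_value_error")
  nr <- vapply(patterns, function(p) nrow(p$points), 0L)
  if (length(unique(nr)) != 1L)
    abort_rdfc("reference patterns must have identical row counts", "rdfc_shape_error")
  stopifnot(all(c("x", "y", "z") %in% names(mapping)))
  structure(list(patterns = patterns,
                 mapping = vapply(mapping[c("x", "y", "z")], as.integer, 0L),
                 provenance = provenance),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> 3 patterns, %d orders; mapping x->%d y->%d z->%d\n",
              nrow(x$patterns[[1]]$points), x$mapping["x"], x$mapping["y"],
              x$mapping["z"]))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> scores (%s), best ref %d (%.3f)%s%s\n",
              paste(sprintf("%.3f", x$scores), collapse = ", "),
              x$best_id, x$best_score,
              if (isTRUE(x$significant)) ", significant" else "",
              if (isTRUE(x$exclusive)) ", exclusive" else ""))
  invisible(x)
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf("<threshold_calibration> threshold %.4f (%g%% of %d null best scores, seed %d)\n",
              x$threshold, x$percentile, x$n_patterns, x$seed))
  invisible(x)
}
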