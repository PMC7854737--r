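# Cohort-level batch analysis, default triplet sets on the 16-electrode
# 10-20 layout, temporal tracking of match scores, seizure-linked reference
# pairs and the periodic-noise robustness experiment.

#' Default 16-electrode 10-20 montage layout
#'
#' Schematic 2D scalp positions (unit head radius, x toward the right ear,
#' y toward the nasion) for the 16 standard lateral 10-20 locations, plus
#' each electrode's mirror across the sagittal midline.
#'
#' @return Data frame with columns `label`, `x`, `y`, `mirror`.
#' @export
montage_1020 <- function() {
  df <- data.frame(
    label = c("Fp1", "Fp2", "F7", "F3", "F4", "F8", "T3", "C3", "C4", "T4",
              "T5", "P3", "P4", "T6", "O1", "O2"),
    x = c(-0.31, 0.31, -0.81, -0.40, 0.40, 0.81, -1.00, -0.45, 0.45, 1.00,
          -0.81, -0.40, 0.40, 0.81, -0.31, 0.31),
    y = c(0.95, 0.95, 0.59, 0.36, 0.36, 0.59, 0.00, 0.00, 0.00, 0.00,
          -0.59, -0.36, -0.36, -0.59, -0.95, -0.95),
    stringsAsFactors = FALSE)
  df$mirror <- c("Fp2", "Fp1", "F8", "F4", "F3", "F7", "T4", "C4", "C3", "T3",
                 "T6", "P4", "P3", "T5", "O2", "O1")
  df
}

#' A named set of electrode triplets
#'
#' @param name set name (`"near"`, `"intermediate"`, `"far"` or custom).
#' @param triplets list of character triples of distinct montage labels.
#' @param separation_class descriptive tag.
#' @return A `triplet_set`.
#' @export
triplet_set <- function(name, triplets, separation_class = name) {
  ok <- vapply(triplets, function(t) length(t) == 3L && !anyDuplicated(t), TRUE)
  if (!all(ok)) abort_rdfc("each triple needs 3 distinct labels", "rdfc_value_error")
  structure(list(name = name, triplets = triplets,
                 separation_class = separation_class),
            class = "triplet_set")
}

#' @export
print.triplet_set <- function(x, ...) {
  cat(sprintf("<triplet_set> '%s': %d triplets (%s)\n", x$name,
              length(x$triplets), x$separation_class))
  invisible(x)
}

mirror_triple <- function(tr, montage) {
  montage$mirror[match(tr, montage$label)]
}

# deterministic mirror-paired selection: candidate unordered triples are
# filtered by a pairwise-distance predicate, ranked, grouped with their
# hemispheric mirrors, and the first `n_pairs` pairs emitted interleaved
# (odd = representative, even = its mirror image)
select_mirror_pairs <- function(montage, keep, rank_key, n_pairs,
                                labels = montage$label) {
  idx <- match(labels, montage$label)
  pos <- as.matrix(montage[idx, c("x", "y")])
  dm <- as.matrix(dist(pos))
  cand <- combn(length(labels), 3L, simplify = FALSE)
  cand <- Filter(function(tr) keep(dm[tr, tr][upper.tri(diag(3))]), cand)
  if (!length(cand)) abort_rdfc("no triples satisfy the separation class",
                                "rdfc_config_error")
  trs <- lapply(cand, function(tr) labels[tr])
  key <- vapply(cand, function(tr) rank_key(dm[tr, tr][upper.tri(diag(3))]), 0)
  ord <- order(key, vapply(trs, function(t) paste(sort(t), collapse = ","), ""))
  trs <- trs[ord]
  seen <- character(0)
  pairs <- list()
  for (tr in trs) {
    k <- paste(sort(tr), collapse = ",")
    if (k %in% seen) next
    mt <- mirror_triple(tr, montage)
    km <- paste(sort(mt), collapse = ",")
    if (km == k) next                   # self-mirror triples cannot be paired
    seen <- c(seen, k, km)
    # representative first: prefer the left-hemisphere copy (sum of x < 0)
    xs <- sum(montage$x[match(tr, montage$label)])
    pairs[[length(pairs) + 1L]] <- if (xs <= 0) list(tr, mt) else list(mt, tr)
    if (length(pairs) == n_pairs) break
  }
  if (length(pairs) < n_pairs)
    abort_rdfc(sprintf("only %d mirror pairs available, %d requested",
                       length(pairs), n_pairs), "rdfc_config_error")
  unlist(pairs, recursive = FALSE)
}

#' Default near / intermediate / far triplet sets
#'
#' Builds the three standard triplet sets from the montage layout. Near
#' triplets are the most compact triangles of mutually neighboring
#' electrodes; intermediate triplets have every pair separated by about two
#' electrode spacings (no adjacent pair); far triplets are drawn from the ten
#' outermost electrode locations with maximal mutual spread. Consecutive odd
#' and even triplets are hemispheric mirror images of each other. The sets
#' are deterministic functions of the layout and fully overridable via
#' [triplet_set()] in a configuration.
#'
#' @param montage layout data frame as from [montage_1020()].
#' @param sizes named sizes of the three sets (defaults 32/32/10; must be
#'   even).
#' @return Named list of three [triplet_set()] objects.
#' @export
triplet_sets_default <- function(montage = montage_1020(),
                                 sizes = c(near = 32L, intermediate = 32L,
                                           far = 10L)) {
  if (!all(c("label", "x", "y", "mirror") %in% names(montage)))
    abort_rdfc("montage must provide label, x, y and mirror columns",
               "rdfc_config_error")
  stopifnot(all(sizes %% 2L == 0L))
  near <- select_mirror_pairs(
    montage, keep = function(d) all(d <= 1.00),
    rank_key = function(d) max(d), n_pairs = sizes[["near"]] / 2L)
  inter <- select_mirror_pairs(
    montage, keep = function(d) all(d > 0.75) && all(d <= 1.45),
    rank_key = function(d) max(d), n_pairs = sizes[["intermediate"]] / 2L)
  ring <- c("Fp1", "Fp2", "F7", "F8", "T3", "T4", "T5", "T6", "O1", "O2")
  far <- select_mirror_pairs(
    montage, keep = function(d) all(d >= 1.15),
    rank_key = function(d) -min(d), n_pairs = sizes[["far"]] / 2L,
    labels = intersect(montage$label, ring))
  list(near = triplet_set("near", near, "neighboring electrodes"),
       intermediate = triplet_set("intermediate", inter,
                                  "separation of two electrodes"),
       far = triplet_set("far", far, "outermost electrode locations"))
}

preprocess_record <- function(record, config) {
  rec <- record
  if (!is.null(config$reference)) rec <- rereference(rec, config$reference)
  if (!is.null(config$band)) rec <- bandpass(rec, config$band[1L], config$band[2L])
  if (!is.null(config$notch) && config$notch > 0 && config$notch < rec$rate / 2)
    rec <- notch(rec, config$notch)
  rec
}

#' Batch rdFC analysis over records and triplet sets
#'
#' Preprocesses each record per the configuration (re-reference, band-pass,
#' notch, epoch selection), computes the pattern of every triplet permutation
#' on the selected epoch, matches it against the reference set, and emits one
#' row per (record, set, triplet, permutation). Per-record failures are
#' logged and skipped; a failing record never aborts the batch. Summary
#' statistics (mean best score and match percentage) are grouped by set and
#' triplet.
#'
#' @param records named list of [eeg_record()] objects.
#' @param sets list of [triplet_set()] objects (e.g.
#'   [triplet_sets_default()]).
#' @param refs a [reference_set()].
#' @param config analysis parameters, see [default_config()].
#' @return List with `matches` (data frame), `summary` (data frame) and
#'   `skipped` (named character vector of error messages).
#' @export
batch_patterns <- function(records, sets, refs, config = default_config()) {
  if (inherits(sets, "triplet_set")) sets <- list(sets)
  if (is.null(names(records)))
    names(records) <- sprintf("record%03d", seq_along(records))
  rows <- list(); skipped <- character(0)
  for (rn in names(records)) {
    ep <- tryCatch({
      rec <- preprocess_record(records[[rn]], config)
      select_epoch(rec, index = config$epoch_index,
                   duration = config$epoch_duration)
    }, rdfc_error = function(e) e)
    if (inherits(ep, "error")) {
      skipped[rn] <- conditionMessage(ep)
      message("skipping record ", rn, ": ", conditionMessage(ep))
      next
    }
    for (st in sets) {
      for (ti in seq_along(st$triplets)) {
        tr <- st$triplets[[ti]]
        for (sq in enumerate_permutations(tr)) {
          res <- best_match(
            compute_pattern(ep, sq, window = config$window,
                            orders = config$orders),
            refs, config$threshold)
          rows[[length(rows) + 1L]] <- data.frame(
            record = rn, set = st$name, triplet_id = ti,
            triplet = paste(tr, collapse = ","),
            permutation_id = sq$permutation_id,
            score1 = res$scores[1L], score2 = res$scores[2L],
            score3 = res$scores[3L], best_id = res$best_id,
            best_score = res$best_score, significant = res$significant,
            exclusive = res$exclusive, stringsAsFactors = FALSE)
        }
      }
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    abort_rdfc("no record produced any pattern", "rdfc_value_error")
  agg <- do.call(rbind, lapply(split(matches, matches[c("set", "triplet_id")],
                                     drop = TRUE), function(g)
    data.frame(set = g$set[1L], triplet_id = g$triplet_id[1L],
               triplet = g$triplet[1L], n = nrow(g),
               mean_score = mean(g$best_score),
               match_pct = 100 * mean(g$significant),
               stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  list(matches = matches, summary = agg[order(agg$set, agg$triplet_id), ],
       skipped = skipped)
}

#' Temporal course of match scores
#'
#' Fixes one permutation of a triplet and recomputes its rdFC pattern on
#' every consecutive non-overlapping epoch of the record, scoring each
#' against all references. Epochs with a flat-lined channel are recorded as
#' missing rather than interpolated.
#'
#' @param record an [eeg_record()] (already preprocessed).
#' @param seq a [triplet_sequence()].
#' @param refs a [reference_set()] (or a `seizure_reference_pair`).
#' @param epoch_len epoch length in seconds (default 300).
#' @param window window length in seconds.
#' @param orders recursion depth.
#' @param threshold significance cutoff stored with the course.
#' @return A `temporal_course`: list with `times` (epoch starts, s), `scores`
#'   (epochs x references matrix, `NA` when missing), `best` (index of the
#'   best reference per epoch), `missing`, plus the sequence metadata.
#' @export
temporal_course <- function(record, seq, refs, epoch_len = 300, window = 1,
                            orders = 5L, threshold = 2.65) {
  pats <- if (inherits(refs, "seizure_reference_pair"))
    list(preictal = refs$preictal, interictal = refs$interictal)
  else refs$patterns
  n_ep <- floor(ncol(record$samples) / (epoch_len * record$rate))
  if (n_ep < 1L) abort_rdfc("record shorter than one epoch", "rdfc_length_error")
  times <- (seq_len(n_ep) - 1L) * epoch_len
  scores <- matrix(NA_real_, nrow = n_ep, ncol = length(pats))
  colnames(scores) <- if (!is.null(names(pats))) names(pats)
                      else paste0("reference", seq_along(pats))
  missing <- logical(n_ep)
  for (k in seq_len(n_ep)) {
    ep <- epoch_at(record, times[k], epoch_len)
    ep$samples <- ep$samples[seq$labels, , drop = FALSE]
    ep$labels <- seq$labels
    if (any(flat_channels(ep$samples, ep$rate))) { missing[k] <- TRUE; next }
    p <- compute_pattern(ep, seq, window = window, orders = orders)
    scores[k, ] <- vapply(pats, function(r) match_score(p, r), 0)
  }
  structure(list(times = times, scores = scores,
                 best = apply(scores, 1L, function(s)
                   if (all(is.na(s))) NA_integer_ else which.max(s)),
                 missing = missing, seq = seq, threshold = threshold,
                 epoch_len = epoch_len),
            class = "temporal_course")
}

#' @export
print.temporal_course <- function(x, ...) {
  cat(sprintf("<temporal_course> %d epochs of %g s, triplet (%s), %d missing\n",
              length(x$times), x$epoch_len, paste(x$seq$labels, collapse = ","),
              sum(x$missing)))
  invisible(x)
}

#' Preictal / interictal reference pair
#'
#' Builds two triplet-specific reference patterns around a seizure: the
#' preictal reference from the epoch ending at seizure onset, and the
#' interictal reference from an epoch starting `offset` seconds (default
#' 4 h = 14,400 s) before onset. Tracking a permutation's match scores
#' against this pair with [temporal_course()] exposes seizure-linked
#' transitions in the connectivity patterns.
#'
#' @param record an [eeg_record()] covering `[onset - offset, onset]`.
#' @param seq a [triplet_sequence()].
#' @param onset seizure onset time (s), e.g. from [read_annotations()].
#' @param offset interictal look-back (s), default 14400.
#' @param epoch_len epoch length in seconds.
#' @param window window length in seconds.
#' @param orders recursion depth.
#' @return A `seizure_reference_pair`: list with `preictal`, `interictal`
#'   ([rdfc_pattern()]s), `onset`, `offset`.
#' @export
seizure_references <- function(record, seq, onset, offset = 14400,
                               epoch_len = 300, window = 1, orders = 5L) {
  if (offset < epoch_len)
    abort_rdfc("offset must be at least one epoch long", "rdfc_param_error")
  if (onset - offset < 0 || onset > ncol(record$samples) / record$rate) {
    max_offset <- onset - epoch_len
    abort_rdfc(sprintf(
      "record does not cover [onset - offset, onset]; maximal achievable offset is %g s",
      max(0, max_offset)), "rdfc_coverage_error")
  }
  take <- function(start) {
    ep <- epoch_at(record, start, epoch_len)
    ep$samples <- ep$samples[seq$labels, , drop = FALSE]
    ep$labels <- seq$labels
    compute_pattern(ep, seq, window = window, orders = orders)
  }
  structure(list(preictal = take(onset - epoch_len),
                 interictal = take(onset - offset),
                 onset = onset, offset = offset),
            class = "seizure_reference_pair")
}

#' @export
print.seizure_reference_pair <- function(x, ...) {
  cat(sprintf("<seizure_reference_pair> onset %g s, interictal %g s prior; preictal-vs-interictal score %.3f\n",
              x$onset, x$offset, match_score(x$preictal, x$interictal)))
  invisible(x)
}

#' Robustness of the match score to periodic noise bursts
#'
#' Emulates periodic artefacts: 2-second bursts of white Gaussian noise are
#' injected every 30 s into a clean epoch at each requested power level
#' (expressed relative to the epoch's mean channel power), the pattern is
#' recomputed and scored against a reference. Because the static summaries
#' integrate over the full 5-minute epoch, short intermittent bursts average
#' out and the score degrades only once the noise power becomes comparable
#' to the signal power.
#'
#' @param epoch a clean [eeg_epoch()].
#' @param seq a [triplet_sequence()].
#' @param ref the reference [rdfc_pattern()] to score against.
#' @param noise_powers numeric vector of noise-to-signal power ratios
#'   (0 means untouched).
#' @param seed RNG seed for the bursts.
#' @param burst_dur burst duration (s), default 2.
#' @param burst_every burst period (s), default 30.
#' @param window window length in seconds.
#' @param orders recursion depth.
#' @return Data frame with columns `noise_power` and `score`.
#' @export
noise_robustness <- function(epoch, seq, ref, noise_powers, seed = 1L,
                             burst_dur = 2, burst_every = 30, window = 1,
                             orders = 5L) {
  tri <- epoch$samples[seq$labels, , drop = FALSE]
  n <- ncol(tri)
  sig_power <- mean(apply(tri, 1L, var))
  n_bursts <- floor(epoch$duration / burst_every)
  burst_idx <- unlist(lapply(seq_len(n_bursts) - 1L, function(k) {
    i0 <- round(k * burst_every * epoch$rate) + 1L
    i0:min(n, i0 + round(burst_dur * epoch$rate) - 1L)
  }))
  scores <- withr::with_seed(seed, vapply(noise_powers, function(pw) {
    noisy <- tri
    if (pw > 0)
      noisy[, burst_idx] <- noisy[, burst_idx] +
        matrix(rnorm(3L * length(burst_idx), sd = sqrt(pw * sig_power)),
               nrow = 3L)
    ep <- eeg_epoch(noisy, epoch$rate, labels = seq$labels,
                    start_time = epoch$start_time, duration = epoch$duration)
    match_score(compute_pattern(ep, seq, window = window, orders = orders), ref)
  }, 0))
  data.frame(noise_power = noise_powers, score = scores)
}
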