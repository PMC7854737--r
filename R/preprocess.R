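# Preprocessing: zero-phase filtering, re-referencing, resampling and epoch
# selection. Filters follow routine clinical practice: Butterworth band-pass
# and a narrow IIR notch, each run forward and backward (filtfilt) so the
# waveform timing is untouched.

# apply a filter per channel, preserving class/metadata of record or epoch
apply_channelwise <- function(x, fun) {
  stopifnot(inherits(x, "eeg_record") || inherits(x, "eeg_epoch"))
  out <- x
  out$samples <- t(apply(x$samples, 1L, fun))
  rownames(out$samples) <- x$labels
  out
}

#' Zero-phase Butterworth band-pass filter
#'
#' Band-pass filters every channel with a 4th-order Butterworth design applied
#' forward and backward (`signal::filtfilt`), giving zero phase distortion.
#' The clinical default band is 0.5--70 Hz.
#'
#' @param x an [eeg_record()] or [eeg_epoch()].
#' @param low,high band edges in Hz; `0 < low < high < rate/2`.
#' @return The filtered object, same class, same dimensions.
#' @export
bandpass <- function(x, low = 0.5, high = 70) {
  rate <- x$rate
  if (!(low > 0 && high > low && high < rate / 2))
    abort_rdfc("band edges must satisfy 0 < low < high < rate/2", "rdfc_param_error")
  bf <- signal::butter(4, c(low, high) / (rate / 2), type = "pass")
  apply_channelwise(x, function(ch) signal::filtfilt(bf, ch))
}

#' Zero-phase IIR notch filter
#'
#' Suppresses power-line interference with a second-order IIR notch (constant
#' quality factor Q = 30), applied forward-backward. Use 50 Hz for recordings
#' from India/Europe and 60 Hz for the USA.
#'
#' @param x an [eeg_record()] or [eeg_epoch()].
#' @param freq notch centre frequency in Hz; `0 < freq < rate/2`.
#' @param Q quality factor (centre frequency / -3 dB bandwidth).
#' @return The filtered object, same class, same dimensions.
#' @export
notch <- function(x, freq = 50, Q = 30) {
  rate <- x$rate
  if (!(freq > 0 && freq < rate / 2))
    abort_rdfc("notch frequency must lie in (0, rate/2)", "rdfc_param_error")
  # standard biquad notch (Audio EQ cookbook)
  w0 <- 2 * pi * freq / rate
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  apply_channelwise(x, function(ch) signal::filtfilt(b, a, ch))
}

# split "A-B" bipolar labels into an edge list
parse_bipolar <- function(labels) {
  parts <- strsplit(labels, "-", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    abort_rdfc("bipolar labels must have the form 'A-B'", "rdfc_montage_error")
  data.frame(anode = vapply(parts, `[`, "", 1L),
             cathode = vapply(parts, `[`, "", 2L),
             channel = seq_along(labels), stringsAsFactors = FALSE)
}

# express every electrode potential against `target` by telescoping bipolar
# channels along the montage graph; fails when the graph does not reach target
bipolar_to_common <- function(record, target) {
  edges <- parse_bipolar(record$labels)
  nodes <- unique(c(edges$anode, edges$cathode))
  if (!target %in% nodes)
    abort_rdfc(sprintf("reference electrode '%s' absent from bipolar montage", target),
               "rdfc_montage_error")
  nt <- ncol(record$samples)
  # potential of each node relative to target, as a signal; BFS over edges
  pot <- vector("list", length(nodes)); names(pot) <- nodes
  pot[[target]] <- numeric(nt)
  frontier <- target
  while (length(frontier)) {
    nxt <- character(0)
    for (nd in frontier) {
      hit <- which(edges$anode == nd | edges$cathode == nd)
      for (i in hit) {
        other <- if (edges$anode[i] == nd) edges$cathode[i] else edges$anode[i]
        if (!is.null(pot[[other]])) next
        sig <- record$samples[edges$channel[i], ]  # anode - cathode
        pot[[other]] <- if (edges$anode[i] == nd) pot[[nd]] - sig else pot[[nd]] + sig
        nxt <- c(nxt, other)
      }
    }
    frontier <- nxt
  }
  unresolved <- nodes[vapply(pot, is.null, TRUE)]
  if (length(unresolved))
    abort_rdfc(sprintf("bipolar montage does not connect to '%s' (unreachable: %s); record skipped",
                       target, paste(unresolved, collapse = ", ")),
               "rdfc_montage_error")
  keep <- setdiff(nodes, target)
  out <- do.call(rbind, pot[c(keep, target)])
  eeg_record(out, record$rate, labels = c(keep, target),
             reference = target, annotations = record$annotations)
}

#' Re-reference an EEG record
#'
#' Transforms all channels to a common reference. `"average"` subtracts the
#' instantaneous mean across channels; `"common:<label>"` re-expresses every
#' channel against one electrode (which becomes the zero signal). Bipolar
#' recordings (labels of the form `"Fp1-F7"`) are converted algebraically by
#' telescoping along the montage chain; an unsolvable montage raises a
#' montage error so the record can be skipped, mirroring clinical practice
#' for incompatible montages.
#'
#' @param record an [eeg_record()] (or [eeg_epoch()] for `"average"`).
#' @param scheme `"average"` or `"common:<label>"`.
#' @return The re-referenced object.
#' @export
rereference <- function(record, scheme) {
  if (identical(scheme, "average")) {
    out <- record
    out$samples <- sweep(record$samples, 2L, colMeans(record$samples))
    if (inherits(out, "eeg_record")) out$reference <- "average"
    return(out)
  }
  if (grepl("^common:", scheme)) {
    target <- sub("^common:", "", scheme)
    if (all(grepl("-", record$labels, fixed = TRUE)))
      return(bipolar_to_common(record, target))
    if (!target %in% record$labels)
      abort_rdfc(sprintf("channel '%s' not present", target), "rdfc_channel_error")
    out <- record
    out$samples <- sweep(record$samples, 2L, record$samples[target, ])
    if (inherits(out, "eeg_record")) out$reference <- target
    return(out)
  }
  abort_rdfc("scheme must be 'average' or 'common:<label>'", "rdfc_param_error")
}

#' Resample an EEG record
#'
#' Anti-aliased rate conversion of every channel in the frequency domain:
#' the spectrum is truncated (downsampling; an ideal anti-alias filter) or
#' zero-padded (upsampling) and inverse-transformed, so no group delay is
#' introduced. Record duration is preserved to within one sample period.
#' Upsampling is permitted but reported with a message, as it adds no
#' information.
#'
#' @param x an [eeg_record()] or [eeg_epoch()].
#' @param target_rate desired sampling rate (Hz).
#' @return The resampled object at `target_rate`.
#' @export
resample <- function(x, target_rate) {
  if (!is.numeric(target_rate) || target_rate <= 0)
    abort_rdfc("target rate must be positive", "rdfc_param_error")
  if (target_rate == x$rate) return(x)
  if (target_rate > x$rate)
    message("upsampling from ", x$rate, " to ", target_rate, " Hz")
  n <- ncol(x$samples)
  m <- floor(n * target_rate / x$rate)
  out <- x
  out$samples <- t(apply(x$samples, 1L, fft_resample, m = m))
  rownames(out$samples) <- x$labels
  out$rate <- target_rate
  if (inherits(out, "eeg_epoch")) out$duration <- m / target_rate
  out
}

# Fourier-domain resampling of one channel from n to m samples
fft_resample <- function(ch, m) {
  n <- length(ch)
  X <- stats::fft(ch)
  Y <- complex(m)
  k <- min(n, m)
  half <- floor((k - 1) / 2)
  Y[1L] <- X[1L]
  if (half > 0) {
    Y[2L:(half + 1L)] <- X[2L:(half + 1L)]
    Y[(m - half + 1L):m] <- X[(n - half + 1L):n]
  }
  if (k %% 2L == 0L) {          # split the shared Nyquist bin symmetrically
    ny <- X[k / 2L + 1L]
    if (m < n) Y[m / 2L + 1L] <- Re(ny)
    else { Y[k / 2L + 1L] <- ny / 2; Y[m - k / 2L + 1L] <- Conj(ny) / 2 }
  }
  Re(stats::fft(Y, inverse = TRUE)) * (m / n) / m
}

#' Detect flat-lined channels
#'
#' A channel is flat when any contiguous segment of at least `min_dur`
#' seconds has zero peak-to-peak amplitude (identical consecutive samples),
#' the signature of a disconnected or saturated electrode. Low-amplitude but
#' fluctuating EEG is not flagged.
#'
#' @param samples channels x time matrix.
#' @param rate sampling rate (Hz).
#' @param min_dur minimum flat duration in seconds (default 1).
#' @return Logical vector, one entry per channel.
#' @export
flat_channels <- function(samples, rate, min_dur = 1) {
  need <- max(2L, round(min_dur * rate))
  apply(samples, 1L, function(ch) {
    r <- rle(ch)
    any(r$lengths >= need)
  })
}

#' Extract an epoch at an arbitrary start time
#'
#' Raw slice of a record, without flat-line checking; [select_epoch()] is the
#' grid-based selector used for cohort analyses.
#'
#' @param record an [eeg_record()].
#' @param start_time epoch start (s from record start).
#' @param duration epoch duration (s).
#' @return An [eeg_epoch()].
#' @export
epoch_at <- function(record, start_time, duration) {
  i0 <- round(start_time * record$rate) + 1L
  i1 <- i0 + round(duration * record$rate) - 1L
  if (i1 > ncol(record$samples))
    abort_rdfc("record does not cover the requested epoch", "rdfc_length_error")
  eeg_epoch(record$samples[, i0:i1, drop = FALSE], record$rate,
            labels = record$labels, start_time = start_time, duration = duration)
}

#' Select an analysis epoch from a record
#'
#' Extracts the `index`-th epoch on a non-overlapping grid anchored at the
#' first sample (epoch k covers [(k-1) D, k D)). The default is the second
#' 5-minute epoch, skipping the calibration sequence at the head of clinical
#' recordings. If the flat-line detector fires on any channel of the
#' requested epoch, the next available epoch is selected automatically and
#' the substitution is flagged on the result.
#'
#' @param record an [eeg_record()].
#' @param index 1-based epoch index (default 2, the "second epoch" rule).
#' @param duration epoch duration in seconds (default 300).
#' @param channels optional subset of channels to check/extract.
#' @return An [eeg_epoch()]; `$substituted` is `TRUE` when a later epoch was
#'   used, and `$start_time` identifies which.
#' @export
select_epoch <- function(record, index = 2L, duration = 300, channels = NULL) {
  n_epochs <- floor(ncol(record$samples) / (duration * record$rate))
  if (n_epochs < 1L)
    abort_rdfc("record shorter than one epoch", "rdfc_length_error")
  if (n_epochs < index)
    abort_rdfc(sprintf("record holds only %d epoch(s), index %d requested",
                       n_epochs, index), "rdfc_length_error")
  sel <- if (is.null(channels)) record$labels else channels
  for (k in index:n_epochs) {
    ep <- epoch_at(record, (k - 1L) * duration, duration)
    if (!any(flat_channels(ep$samples[sel, , drop = FALSE], ep$rate))) {
      ep$samples <- ep$samples[sel, , drop = FALSE]
      ep$labels <- sel
      ep$substituted <- (k != index)
      return(ep)
    }
  }
  abort_rdfc("no epoch free of flat-lined channels", "rdfc_no_valid_epoch_error")
}
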