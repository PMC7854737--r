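# EDF (European Data Format, 16-bit) and plain tabular input/output.
# The EDF implementation covers the standard fixed-width header and
# contiguous int16 data records, which is all clinical scalp EEG needs here.

pad <- function(s, n) formatC(substr(s, 1L, n), width = -n)

#' Write an EEG record or epoch to disk
#'
#' Writes EDF (16-bit, one-second data records) or a tab-separated samples
#' file with metadata header lines. EDF quantizes each channel onto its
#' physical range with 16-bit resolution, so a write-read round trip agrees
#' to within one quantization step.
#'
#' @param x an [eeg_record()] or [eeg_epoch()].
#' @param path output file path.
#' @param format `"edf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(x, path, format = c("edf", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") return(write_record_tsv(x, path))
  samples <- x$samples
  rate <- x$rate
  if (abs(rate - round(rate)) > 1e-9)
    abort_rdfc("EDF writer requires an integer sampling rate", "rdfc_param_error")
  rate <- as.integer(round(rate))
  ns <- nrow(samples)
  spr <- rate                       # samples per 1-s data record
  nrec <- ceiling(ncol(samples) / spr)
  if (ncol(samples) < nrec * spr) { # pad the final partial record
    padn <- nrec * spr - ncol(samples)
    samples <- cbind(samples, samples[, rep(ncol(samples), padn), drop = FALSE])
  }
  pmin_ <- apply(samples, 1L, min); pmax_ <- apply(samples, 1L, max)
  fix <- pmax_ - pmin_ < 1e-12
  pmax_[fix] <- pmin_[fix] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb"); on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  writeChar(paste0(
    pad("0", 8), pad("X X X X", 80), pad("Startdate X X X X", 80),
    pad("01.01.00", 8), pad("00.00.00", 8), pad(as.character(hdr_bytes), 8),
    pad("", 44), pad(as.character(nrec), 8), pad("1", 8),
    pad(as.character(ns), 4),
    paste(vapply(x$labels, pad, "", 16), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad("uV", 8), ns), collapse = ""),
    paste(vapply(sprintf("%.6g", pmin_), pad, "", 8), collapse = ""),
    paste(vapply(sprintf("%.6g", pmax_), pad, "", 8), collapse = ""),
    paste(rep(pad(as.character(dmin), 8), ns), collapse = ""),
    paste(rep(pad(as.character(dmax), 8), ns), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad(as.character(spr), 8), ns), collapse = ""),
    paste(rep(pad("", 32), ns), collapse = "")), con, eos = NULL)
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (s in seq_len(ns)) {
      d <- round((samples[s, idx] - pmin_[s]) * scale[s]) + dmin
      writeBin(as.integer(pmin(dmax, pmax(dmin, d))), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

write_record_tsv <- function(x, path) {
  con <- file(path, "w"); on.exit(close(con))
  ref <- if (!is.null(x$reference)) x$reference else "unknown"
  writeLines(c(sprintf("# rate=%.10g", x$rate),
               sprintf("# reference=%s", ref),
               sprintf("# start_time=%.10g",
                       if (!is.null(x$start_time)) x$start_time else 0)), con)
  df <- as.data.frame(t(x$samples))
  names(df) <- x$labels
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_field <- function(raw, at, n) {
  trimws(rawToChar(raw[(at + 1L):(at + n)]))
}

read_edf <- function(path) {
  sz <- file.size(path)
  if (is.na(sz) || sz < 256) abort_rdfc("not a readable EDF file", "rdfc_format_error")
  raw <- readBin(path, "raw", n = sz)
  ns <- suppressWarnings(as.integer(read_field(raw, 252, 4)))
  hdr_bytes <- suppressWarnings(as.integer(read_field(raw, 184, 8)))
  nrec <- suppressWarnings(as.integer(read_field(raw, 236, 8)))
  dur <- suppressWarnings(as.numeric(read_field(raw, 244, 8)))
  if (anyNA(c(ns, hdr_bytes, nrec, dur)) || ns < 1L)
    abort_rdfc("corrupt EDF header", "rdfc_format_error")
  fld <- function(offset, width) {
    vapply(seq_len(ns) - 1L, function(i)
      read_field(raw, 256L + offset * ns + i * width, width), "")
  }
  labels <- fld(0L, 16L)
  if (any(!nzchar(labels)))
    abort_rdfc("EDF header lacks channel labels", "rdfc_metadata_error")
  pmin_ <- as.numeric(fld(16L + 80L + 8L, 8L))
  pmax_ <- as.numeric(fld(16L + 80L + 8L + 8L, 8L))
  dmin <- as.numeric(fld(16L + 80L + 8L + 16L, 8L))
  dmax <- as.numeric(fld(16L + 80L + 8L + 24L, 8L))
  spr <- as.integer(fld(16L + 80L + 8L + 32L + 80L, 8L))
  need <- hdr_bytes + 2 * nrec * sum(spr)
  if (sz < need) abort_rdfc("truncated EDF file", "rdfc_format_error")
  d <- readBin(raw[(hdr_bytes + 1L):need], "integer", n = nrec * sum(spr),
               size = 2L, endian = "little")
  samples <- matrix(0, nrow = ns, ncol = nrec * spr[1L])
  offs <- c(0L, cumsum(spr))
  per_rec <- sum(spr)
  for (s in seq_len(ns)) {
    idx <- as.vector(outer(seq_len(spr[s]) + offs[s], (seq_len(nrec) - 1L) * per_rec, `+`))
    samples[s, ] <- (d[idx] - dmin[s]) * (pmax_[s] - pmin_[s]) / (dmax[s] - dmin[s]) + pmin_[s]
  }
  rate <- spr[1L] / dur
  eeg_record(samples, rate, labels = labels)
}

read_record_tsv <- function(path) {
  hdr <- readLines(path, n = 10L)
  meta <- hdr[startsWith(hdr, "# ")]
  getm <- function(key, default) {
    hit <- grep(paste0("^# ", key, "="), meta, value = TRUE)
    if (!length(hit)) return(default)
    sub(paste0("^# ", key, "="), "", hit[1L])
  }
  rate <- as.numeric(getm("rate", NA))
  if (is.na(rate)) abort_rdfc("tabular record lacks '# rate=' header", "rdfc_metadata_error")
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE)
  eeg_record(t(as.matrix(df)), rate, labels = names(df),
             reference = getm("reference", "unknown"))
}

#' Read an EEG record from disk
#'
#' Reads EDF (the primary clinical format) or the package's tab-separated
#' samples format. Annotations, when stored alongside as a two-column text
#' file, can be attached with [read_annotations()].
#'
#' @param path input file path.
#' @param format `"edf"` or `"tsv"`; guessed from the extension by default.
#' @return An [eeg_record()].
#' @export
read_record <- function(path, format = NULL) {
  if (!file.exists(path)) abort_rdfc("file not found", "rdfc_format_error")
  if (is.null(format))
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "tsv"
  switch(format, edf = read_edf(path), tsv = read_record_tsv(path),
         abort_rdfc(paste0("unsupported format '", format, "'"), "rdfc_format_error"))
}

#' Read / write annotation events
#'
#' Annotations are kept dataset-agnostic: a two-column whitespace-separated
#' text file of onset time (seconds from record start) and label, e.g.
#' seizure onsets.
#'
#' @param path text file path.
#' @return `read_annotations` returns a data frame with columns `onset` and
#'   `label`; `write_annotations` returns `path` invisibly.
#' @export
read_annotations <- function(path) {
  df <- read.table(path, header = FALSE, col.names = c("onset", "label"),
                   colClasses = c("numeric", "character"))
  df
}

#' @rdname read_annotations
#' @param annotations data frame with columns `onset` and `label`.
#' @export
write_annotations <- function(annotations, path) {
  write.table(data.frame(onset = sprintf("%.10g", annotations$onset),
                         label = annotations$label),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read an analysis configuration file
#'
#' YAML configuration declaring band edges, notch frequency, epoch duration
#' and index, re-reference scheme, window length, order count and optional
#' custom triplet sets. Missing keys fall back to [default_config()].
#'
#' @param path YAML file path; `NULL` returns the defaults.
#' @return A named list of analysis parameters.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  cfg[names(user)] <- user
  cfg
}

#' @rdname read_config
#' @export
default_config <- function() {
  list(band = c(0.5, 70), notch = 50, epoch_duration = 300, epoch_index = 2L,
       reference = NULL, window = 1, orders = 5L, threshold = 2.65)
}
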