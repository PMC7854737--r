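# Shared fixtures, generated in code at test time.

# scaled-down EEG-like coupling spec: same mixing geometry as the package
# default, shorter and at a lower rate so a pattern costs milliseconds
small_spec <- function(seed = 1L, rate = 64, duration = 30, ...) {
  sp <- default_reference_spec(seed = seed, rate = rate, duration = duration)
  extra <- list(...)
  sp[names(extra)] <- extra
  sp
}

# naive reference implementation of the full recursion: every window is
# recomputed from scratch with stats::cor; independent of the rolling-sum path
naive_pattern <- function(tri, window, orders = 5L) {
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  static3 <- function(m) vapply(1:3, function(k)
    cor(m[pairs[k, 1], ], m[pairs[k, 2], ]), 0)
  pts <- matrix(NA_real_, orders, 3)
  pts[1, ] <- static3(tri)
  series <- tri
  for (n in seq_len(orders - 1L)) {
    L <- ncol(series) - window + 1L
    series <- sapply(seq_len(L), function(t) vapply(1:3, function(k)
      cor(series[pairs[k, 1], t:(t + window - 1L)],
          series[pairs[k, 2], t:(t + window - 1L)]), 0))
    pts[n + 1L, ] <- static3(series)
  }
  pts
}

# a generic nondegenerate pattern for matching tests
generic_pattern <- function(seed = 4L) {
  pts <- withr::with_seed(seed, matrix(runif(15, -1, 1), ncol = 3))
  rdfc_pattern(pts)
}

# 16-channel montage record: a shared source plus channel noise so every
# triplet has nondegenerate connectivity
montage_record <- function(seed = 1L, rate = 64, duration = 20) {
  n <- rate * duration
  labels <- montage_1020()$label
  bf <- signal::butter(4, c(0.5, 0.45 * rate) / (rate / 2), type = "pass")
  withr::with_seed(seed, {
    common <- signal::filtfilt(bf, rnorm(n))
    common <- common / sd(common)
    env <- 1 + 0.8 * sin(2 * pi * 0.2 * (seq_len(n) - 1) / rate)
    samples <- t(sapply(seq_along(labels), function(i) {
      own <- signal::filtfilt(bf, rnorm(n))
      (0.5 + 0.05 * i) * env * common + own / sd(own)
    }))
    eeg_record(samples, rate, labels = labels, reference = "average")
  })
}
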