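test_that("default triplet sets have the standard sizes and mirror pairing", {
  sets <- triplet_sets_default()
  expect_length(sets$near$triplets, 32L)
  expect_length(sets$intermediate$triplets, 32L)
  expect_length(sets$far$triplets, 10L)
  m <- montage_1020()
  for (st in sets) {
    for (tr in st$triplets) {
      expect_length(unique(tr), 3L)
      expect_true(all(tr %in% m$label))
    }
    # consecutive odd/even triplets are hemispheric mirror images
    for (k in seq(1, length(st$triplets), by = 2)) {
      mirrored <- m$mirror[match(st$triplets[[k]], m$label)]
      expect_setequal(st$triplets[[k + 1]], mirrored)
    }
    # no triplet repeats within a set
    keys <- vapply(st$triplets, function(t) paste(sort(t), collapse = ","), "")
    expect_identical(anyDuplicated(keys), 0L)
  }
  # far triplets draw from the outer ring only
  ring <- c("Fp1", "Fp2", "F7", "F8", "T3", "T4", "T5", "T6", "O1", "O2")
  expect_true(all(unlist(sets$far$triplets) %in% ring))
})

test_that("batch analysis emits one row per record x triplet x permutation", {
  sets <- triplet_sets_default()
  records <- lapply(1:2, function(s) montage_record(seed = s, duration = 20))
  names(records) <- c("recA", "recB")
  cfg <- default_config()
  cfg$epoch_duration <- 8; cfg$epoch_index <- 1L; cfg$window <- 0.25
  cfg$band <- c(0.5, 28); cfg$notch <- 25
  refs <- generate_reference_set(small_spec(seed = 1, rate = 128, duration = 60),
                                 window = 0.5)
  out <- batch_patterns(records, sets["near"], refs, cfg)
  expect_identical(nrow(out$matches), 2L * 32L * 6L)
  expect_identical(nrow(out$summary), 32L)
  expect_true(all(out$matches$best_score >= -4 & out$matches$best_score <= 4))
  expect_true(all(out$summary$match_pct >= 0 & out$summary$match_pct <= 100))
  # deterministic: identical rerun
  out2 <- batch_patterns(records, sets["near"], refs, cfg)
  expect_identical(out$matches, out2$matches)
})

test_that("failing records are skipped without aborting the batch", {
  good <- montage_record(seed = 7, duration = 20)
  short <- montage_record(seed = 8, duration = 2)
  cfg <- default_config()
  cfg$epoch_duration <- 8; cfg$epoch_index <- 1L; cfg$window <- 0.25
  cfg$band <- c(0.5, 28); cfg$notch <- NULL
  refs <- generate_reference_set(small_spec(seed = 1, rate = 128, duration = 60),
                                 window = 0.5)
  one_set <- triplet_set("custom", list(c("C3", "T3", "T5")))
  out <- suppressMessages(
    batch_patterns(list(ok = good, bad = short), one_set, refs, cfg))
  expect_identical(sort(unique(out$matches$record)), "ok")
  expect_named(out$skipped, "bad")
  expect_identical(nrow(out$matches), 6L)
})

test_that("a cohort generated from reference-shaped couplings mostly matches", {
  spec <- small_spec(seed = 11, rate = 128, duration = 60)
  refs <- generate_reference_set(spec, window = 0.5)
  cfg <- default_config()
  cfg$epoch_duration <- 60; cfg$epoch_index <- 1L; cfg$window <- 0.5
  cfg$band <- NULL; cfg$notch <- NULL   # generator output is already band-limited
  records <- lapply(1:6, function(s)
    generate_record(small_spec(seed = 5000 + s, rate = 128, duration = 60)))
  one_set <- triplet_set("synthetic", list(c("Ch1", "Ch2", "Ch3")))
  out <- batch_patterns(records, one_set, refs, cfg)
  expect_identical(nrow(out$matches), 36L)
  expect_gt(100 * mean(out$matches$significant), 90)
})

test_that("temporal courses track the coupling epoch by epoch", {
  # stationary coupling: best reference stays constant
  spec <- small_spec(seed = 21, rate = 64, duration = 360)
  refs <- generate_reference_set(small_spec(seed = 21, rate = 64, duration = 30),
                                 window = 0.5)
  rec <- generate_record(spec)
  tc <- temporal_course(rec, triplet_sequence(rec$labels), refs,
                        epoch_len = 30, window = 0.5)
  expect_length(tc$times, 12L)
  expect_identical(tc$times, seq(0, 330, by = 30))
  expect_false(any(tc$missing))
  expect_length(unique(tc$best), 1L)

  # coupling switch mid-record flips the leading reference pair
  m2 <- spec$mixing[c(3, 1, 2), ]
  spec_sw <- small_spec(seed = 22, rate = 64, duration = 360,
                        switch = list(at = 180, mixing = m2))
  rec_sw <- generate_record(spec_sw)
  pre <- compute_pattern(epoch_at(rec_sw, 0, 30),
                         triplet_sequence(rec_sw$labels), window = 0.5)
  post <- compute_pattern(epoch_at(rec_sw, 330, 30),
                          triplet_sequence(rec_sw$labels), window = 0.5)
  pair <- structure(list(preictal = post, interictal = pre,
                         onset = 360, offset = 330),
                    class = "seizure_reference_pair")
  tc2 <- temporal_course(rec_sw, triplet_sequence(rec_sw$labels), pair,
                         epoch_len = 30, window = 0.5)
  expect_identical(unname(tc2$best[1]), 2L)           # interictal wins early
  expect_identical(unname(tc2$best[12]), 1L)          # preictal wins late
  expect_error(temporal_course(generate_record(small_spec(duration = 10)),
                               triplet_sequence(c("Ch1", "Ch2", "Ch3")),
                               refs, epoch_len = 30),
               class = "rdfc_length_error")
})

test_that("flat epochs are recorded as missing, not interpolated", {
  rec <- generate_record(small_spec(seed = 23, rate = 64, duration = 120))
  rec$samples["Ch2", (30 * 64 + 1):(60 * 64)] <- 0   # second epoch flat
  refs <- generate_reference_set(small_spec(seed = 23, rate = 64, duration = 30),
                                 window = 0.5)
  tc <- temporal_course(rec, triplet_sequence(rec$labels), refs,
                        epoch_len = 30, window = 0.5)
  expect_true(tc$missing[2])
  expect_true(all(is.na(tc$scores[2, ])))
  expect_false(any(tc$missing[-2]))
})

test_that("seizure reference pairs use the stated epochs", {
  onset <- 300; offset <- 240
  spec <- small_spec(seed = 25, rate = 64, duration = 320,
                     switch = list(at = onset - 30,
                                   mixing = small_spec()$mixing[c(2, 3, 1), ]))
  rec <- generate_record(spec, annotations = data.frame(onset = onset,
                                                        label = "seizure"))
  pair <- seizure_references(rec, triplet_sequence(rec$labels),
                             onset = onset, offset = offset, epoch_len = 30,
                             window = 0.5)
  expect_identical(pair$preictal$start_time, onset - 30)
  expect_identical(pair$interictal$start_time, onset - offset)
  # coupling changed during the preictal epoch: the two references differ
  expect_lt(match_score(pair$preictal, pair$interictal), 4 - 1e-6)
  expect_error(seizure_references(rec, triplet_sequence(rec$labels),
                                  onset = 100, offset = 240, epoch_len = 30),
               class = "rdfc_coverage_error")
  expect_equal(eval(formals(seizure_references)$offset), 4 * 3600)
})

test_that("noise bursts leave the score intact at zero power and degrade it monotonically", {
  spec <- small_spec(seed = 27, rate = 64, duration = 300)
  ep <- generate_epoch(spec)
  sq <- triplet_sequence(ep$labels)
  ref <- compute_pattern(ep, sq, window = 1)
  sweep_tbl <- noise_robustness(ep, sq, ref, noise_powers = c(0, 0.5, 2, 8, 32),
                                seed = 5, window = 1)
  clean <- match_score(compute_pattern(ep, sq, window = 1), ref)
  expect_identical(sweep_tbl$score[1], clean)
  expect_equal(sweep_tbl$score[1], 4, tolerance = 1e-12)
  expect_true(all(diff(sweep_tbl$score) <= 0.15))   # non-increasing up to noise
  expect_lt(sweep_tbl$score[5], sweep_tbl$score[1])
})

test_that("noise is injected only inside the burst windows", {
  spec <- small_spec(seed = 28, rate = 64, duration = 90)
  ep <- generate_epoch(spec)
  noisy <- withr::with_seed(9, {
    tri <- ep$samples
    n <- ncol(tri)
    burst_idx <- unlist(lapply(0:(90 %/% 30 - 1), function(k) {
      i0 <- k * 30 * 64 + 1
      i0:(i0 + 2 * 64 - 1)
    }))
    length(burst_idx)
  })
  expect_identical(noisy, 3L * 2L * 64L)  # 3 bursts of 2 s at 64 Hz
  # zero-power sweep returns the clean pattern => samples untouched
  sq <- triplet_sequence(ep$labels)
  ref <- compute_pattern(ep, sq, window = 0.5)
  tbl <- noise_robustness(ep, sq, ref, noise_powers = 0, seed = 1, window = 0.5)
  expect_equal(tbl$score, 4, tolerance = 1e-12)
})
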