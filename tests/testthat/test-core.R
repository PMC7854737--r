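test_that("sliding correlation matches a per-window Pearson oracle", {
  withr::with_seed(11, {
    a <- rnorm(200); b <- rnorm(200)
  })
  w <- 16L
  got <- sliding_correlation(a, b, w)
  want <- vapply(seq_len(200 - w + 1L), function(t)
    cor(a[t:(t + w - 1L)], b[t:(t + w - 1L)]), 0)
  expect_lt(max(abs(got - want)), 1e-10)
  expect_length(got, 200 - w + 1L)
})

test_that("sliding correlation handles perfect, anti- and degenerate coupling", {
  s <- sin(seq(0, 10, length.out = 300))
  expect_true(all(sliding_correlation(s, s, 32) == 1))
  expect_true(all(sliding_correlation(s, -s, 32) == -1))
  flat <- c(rep(1, 64), rnorm(100))
  r <- sliding_correlation(flat, rnorm(164), 32)
  expect_gt(attr(r, "n_degenerate"), 0)
  expect_true(all(r[1:10] == 0))       # constant windows take the value 0
  expect_error(sliding_correlation(s, s, 400), class = "rdfc_length_error")
  expect_error(sliding_correlation(s, s[-1], 32), class = "rdfc_length_error")
})

test_that("output length follows floor((N - W)/step) + 1 at epoch scale", {
  a <- rnorm(76800); b <- rnorm(76800)
  expect_length(sliding_correlation(a, b, 256L), 76545L)
  expect_length(sliding_correlation(a, b, 256L, step = 10L), 7655L)
})

test_that("dfc_step rows follow the pairing convention", {
  s <- rnorm(400)
  same <- rbind(s, s, s)
  st <- dfc_step(same, 32)
  expect_true(all(st$series == 1))
  flip <- rbind(s, s, -s)
  st2 <- dfc_step(flip, 32)
  expect_true(all(st2$series["x", ] == 1))
  expect_true(all(st2$series["y", ] == -1))
  expect_true(all(st2$series["z", ] == -1))
  # compositional: rows equal independent sliding_correlation calls
  tri <- matrix(rnorm(3 * 300), nrow = 3)
  st3 <- dfc_step(tri, 25)
  expect_equal(st3$series["x", ], as.numeric(sliding_correlation(tri[1, ], tri[2, ], 25)))
  expect_equal(st3$series["y", ], as.numeric(sliding_correlation(tri[1, ], tri[3, ], 25)))
  expect_equal(st3$series["z", ], as.numeric(sliding_correlation(tri[2, ], tri[3, ], 25)))
})

test_that("static summary equals the textbook Pearson formula", {
  s <- rnorm(500)
  expect_equal(unname(static_summary(rbind(s, s, s))), c(1, 1, 1))
  expect_equal(unname(static_summary(rbind(s, -s, s))), c(-1, 1, -1))
  tri <- matrix(rnorm(1500), nrow = 3)
  pearson <- function(u, v) {
    du <- u - mean(u); dv <- v - mean(v)
    sum(du * dv) / sqrt(sum(du^2) * sum(dv^2))
  }
  got <- static_summary(tri)
  expect_equal(unname(got),
               c(pearson(tri[1, ], tri[2, ]), pearson(tri[1, ], tri[3, ]),
                 pearson(tri[2, ], tri[3, ])),
               tolerance = 1e-12)
  expect_error(static_summary(tri[, 1, drop = FALSE]), class = "rdfc_length_error")
})

test_that("full recursion matches naive per-window recomputation on short signals", {
  for (trial in 1:6) {
    n <- withr::with_seed(trial, sample(100:200, 1))
    tri <- withr::with_seed(100 + trial, matrix(rnorm(3 * n), nrow = 3))
    w <- c(8L, 12L, 16L)[(trial %% 3L) + 1L]
    ep <- eeg_epoch(tri, rate = 1, labels = c("a", "b", "c"))
    got <- compute_pattern(ep, c("a", "b", "c"), window = w)$points
    want <- naive_pattern(tri, w)
    expect_lt(max(abs(got - want)), 1e-8)
  }
})

test_that("patterns of independent noise start near the origin and stay in range", {
  n <- 20000L
  tri <- withr::with_seed(5, matrix(rnorm(3 * n), nrow = 3))
  ep <- eeg_epoch(tri, rate = 100, labels = c("a", "b", "c"))
  p <- compute_pattern(ep, c("a", "b", "c"), window = 0.5)
  expect_true(all(abs(p$points[1, ]) < 3 / sqrt(n)))
  expect_true(all(p$points >= -1 & p$points <= 1))
})

test_that("orders beyond five shrink toward the origin", {
  ep <- generate_epoch(small_spec(seed = 9, duration = 60))
  p <- compute_pattern(ep, ep$labels, window = 0.5, orders = 20L)
  expect_identical(nrow(p$points), 20L)
  early <- mean(abs(p$points[1:3, ]))
  late <- mean(abs(p$points[16:20, ]))
  expect_lt(late, early)
})

test_that("compute_pattern validates channels and length", {
  ep <- generate_epoch(small_spec(duration = 10))
  expect_error(compute_pattern(ep, c("Ch1", "Ch2", "Nope")),
               class = "rdfc_channel_error")
  short_ep <- eeg_epoch(matrix(rnorm(3 * 50), nrow = 3), rate = 64,
                        labels = c("a", "b", "c"))
  expect_error(compute_pattern(short_ep, c("a", "b", "c"), window = 1),
               class = "rdfc_length_error")
})

test_that("order-n series length is L0 - n (W - 1)", {
  L0 <- 3000L; W <- 40L
  series <- matrix(rnorm(3 * L0), nrow = 3)
  for (n in 1:4) {
    series <- dfc_step(series, W)$series
    expect_identical(ncol(series), L0 - n * (W - 1L))
  }
})

test_that("permutation of the electrode sequence permutes pattern coordinates lawfully", {
  ep <- generate_epoch(small_spec(seed = 3, duration = 20))
  base <- compute_pattern(ep, triplet_sequence(ep$labels, 1L), window = 0.5)
  # induced pair permutation of a channel/series arrangement (slot i <- item tau[i])
  induced <- function(tau) {
    pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
    vapply(1:3, function(k) {
      got <- sort(tau[pairs[k, ]])
      which(apply(pairs, 1, function(pr) all(pr == got)))
    }, 0L)
  }
  perms <- list(c(1L, 3L, 2L), c(2L, 1L, 3L), c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  for (tau in perms) {
    got <- compute_pattern(ep, triplet_sequence(ep$labels[tau]), window = 0.5)
    sigma <- induced(tau)
    predicted <- base$points
    for (n in seq_len(nrow(predicted))) {
      predicted[n, ] <- base$points[n, sigma]
      sigma <- induced(sigma)
    }
    expect_lt(max(abs(got$points - predicted)), 1e-10)
    for (n in seq_len(nrow(predicted)))   # per-order coordinate multisets
      expect_equal(sort(got$points[n, ]), sort(base$points[n, ]),
                   ignore_attr = TRUE)
  }
})

test_that("patterns are invariant to per-channel affine rescaling", {
  ep <- generate_epoch(small_spec(seed = 6, duration = 20))
  p1 <- compute_pattern(ep, ep$labels, window = 0.5)
  ep2 <- ep
  ep2$samples <- ep$samples * c(3.7, 0.2, 12) + c(-5, 40, 0.3)
  p2 <- compute_pattern(ep2, ep2$labels, window = 0.5)
  expect_lt(max(abs(p1$points - p2$points)), 1e-9)
})

test_that("the six permutations enumerate deterministically", {
  perms <- enumerate_permutations(c("C3", "T3", "T5"))
  expect_length(perms, 6L)
  expect_identical(perms[[1]]$labels, c("C3", "T3", "T5"))
  expect_identical(perms[[1]]$permutation_id, 1L)
  seqs <- vapply(perms, function(p) paste(p$labels, collapse = ","), "")
  expect_true("C3,T5,T3" %in% seqs)
  expect_identical(anyDuplicated(seqs), 0L)
  expect_error(enumerate_permutations(c("C3", "C3", "T5")), class = "rdfc_value_error")
})

test_that("static measure counts follow the pairwise recursion", {
  expect_identical(count_static_measures(3, 5), 15)
  expect_identical(count_static_measures(4, 5), 6 + 15 + 105 + 5460 + 14903070)
  expect_gt(count_static_measures(4, 5), 1.49e7)
  expect_identical(count_static_measures(2, 4), 1)
})

test_that("patterns round-trip through tabular and JSON serialization", {
  ep <- generate_epoch(small_spec(seed = 2, duration = 10))
  pats <- lapply(enumerate_permutations(ep$labels), function(sq)
    compute_pattern(ep, sq, window = 0.5))
  for (fmt in c("tsv", "json")) {
    f <- tempfile(fileext = paste0(".", fmt))
    write_patterns(pats, f, format = fmt)
    back <- read_patterns(f)
    expect_length(back, 6L)
    for (i in 1:6) {
      expect_equal(back[[i]]$points, pats[[i]]$points, tolerance = 1e-15)
      expect_identical(back[[i]]$labels, pats[[i]]$labels)
      expect_identical(back[[i]]$permutation_id, pats[[i]]$permutation_id)
    }
    unlink(f)
  }
})
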