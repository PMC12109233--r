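test_that("constant-Q spectrogram localises pitch per semitone bin", {
  sr <- 8000
  t <- seq(0, 3, by = 1 / sr)
  a4 <- sin(2 * pi * 440 * t)
  cq <- cqt_spectrogram(a4, sr)
  expect_equal(nrow(cq$frames), 73)   # C1..C7 inclusive, one per semitone
  a4_bin <- which.min(abs(cq$bin_freqs - 440))
  interior <- 15:(ncol(cq$frames) - 15)
  expect_true(all(apply(cq$frames[, interior], 2, which.max) == a4_bin))
  expect_equal(diff(cq$frame_times[1:2]), 0.023, tolerance = 1e-9)

  silence <- cqt_spectrogram(rep(0, 2 * sr), sr)
  expect_true(all(silence$frames < 1e-12))

  # doubling the amplitude scales every bin up
  cq2 <- cqt_spectrogram(2 * a4, sr)
  expect_true(all(cq2$frames[, interior] >= cq$frames[, interior] - 1e-12))
  expect_equal(max(cq2$frames), 2 * max(cq$frames), tolerance = 1e-6)

  expect_error(cqt_spectrogram(numeric(), sr), "empty")
  expect_error(cqt_spectrogram(a4, sr, high_pitch = "C9"), "Nyquist")
})

test_that("wav files round-trip through the reader", {
  sr <- 8000
  tone <- 0.5 * sin(2 * pi * 220 * seq(0, 1.5, by = 1 / sr))
  f <- tempfile(fileext = ".wav")
  write_wav(tone, sr, f)
  w <- read_wav(f)
  expect_equal(w$sample_rate, sr)
  expect_equal(w$samples, tone, tolerance = 1e-4)   # 16-bit quantisation
})

test_that("dtw of a matrix with itself is the diagonal at zero cost", {
  set.seed(21)
  fa <- spectro_features(matrix(runif(24 * 60), 24), 0.023)
  w <- dtw_align(fa, fa)
  expect_equal(attr(w, "cost"), 0, tolerance = 1e-9)
  expect_equal(w$t_b, w$t_a)
  path <- attr(w, "path")
  expect_equal(path[, 1], path[, 2])
})

test_that("compiled dtw agrees with the plain-R dynamic programme", {
  set.seed(22)
  for (metric in c("cosine", "euclidean")) {
    A <- matrix(runif(12 * 30), 12)
    idx <- c(1:10, 10:20, 20:30)
    B <- pmax(A[, idx] + matrix(rnorm(12 * length(idx), 0, 0.01), 12), 0)
    fa <- spectro_features(A, 0.023)
    fb <- spectro_features(B, 0.023)
    w <- dtw_align(fa, fb, metric = metric, smooth = 0)
    or <- oracle_dtw(A, B, metric)
    expect_equal(attr(w, "cost"), or$cost, tolerance = 1e-9)
    expect_equal(unname(attr(w, "path")), unname(or$path))
  }
})

test_that("frame doubling halves the fitted warp slope", {
  set.seed(23)
  A <- matrix(runif(20 * 120), 20)
  fa <- spectro_features(A, 0.023)
  fb <- spectro_features(A[, rep(1:120, each = 2)], 0.023)
  w <- dtw_align(fa, fb)
  slope <- stats::coef(stats::lm(w$t_a ~ w$t_b))[2]
  expect_equal(unname(slope), 0.5, tolerance = 0.023)
})

test_that("alignment recovers the generator's tempo curve within 2 hops", {
  ev <- annotation_track(c(5, 12, 20, 33, 41, 50), sprintf("e%d", 1:6),
                         "entry")
  curve <- tempo_curve_pl(c(0, 20, 55), c(0.8, 1.25))
  pp <- generate_performance_pair(ev, curve, seed = 3, duration_a = 55)
  w <- dtw_align(pp$features_a, pp$features_b)
  hop <- pp$features_a$hop
  rec <- warp_times(w, pp$track_b$time)
  expect_true(all(abs(rec - ev$time) <= 2 * hop))
  tb <- pp$warp$t_b
  keep <- tb >= min(w$t_b) & tb <= max(w$t_b)
  expect_true(all(abs(warp_times(w, tb[keep]) - pp$warp$t_a[keep])
                  <= 2 * hop))

  expect_error(
    dtw_align(pp$features_a,
              spectro_features(pp$features_b$frames[1:10, ], 0.023)),
    "bin count")
})

test_that("warp_times interpolates, clamps, and preserves order", {
  idm <- warp_map(c(0, 10), c(0, 10))
  expect_equal(warp_times(idm, c(1, 4, 7)), c(1, 4, 7))

  m <- warp_map(c(0, 10), c(0, 20))
  expect_equal(warp_times(m, 5), 10)

  set.seed(24)
  x <- sort(runif(20, 0, 10))
  expect_true(all(diff(warp_times(m, x)) >= 0))
  expect_warning(warp_times(m, 15), "clamped")
  expect_error(warp_times(idm, numeric(0)) -> e0, NA)
  expect_length(e0, 0)
})

test_that("warping forth and back returns the original times", {
  ev <- annotation_track(c(4, 11, 19, 27), letters[1:4], "entry")
  curve <- tempo_curve_pl(c(0, 15, 32), c(1.2, 0.85))
  pp <- generate_performance_pair(ev, curve, seed = 5, duration_a = 32)
  w <- dtw_align(pp$features_a, pp$features_b)
  hop <- pp$features_a$hop
  tb <- seq(2, min(max(w$t_b), curve(32)) - 2, by = 0.5)
  back <- warp_times(invert_warp(w), warp_times(w, tb))
  expect_true(all(abs(back - tb) <= 2 * hop))
})

test_that("held passages are the maximal long inter-onset gaps", {
  tr <- annotation_track(c(0, 2, 9, 10), c("a", "b", "c", "d"), "entry")
  hp <- detect_held_passages(tr, 3)
  expect_equal(hp$start, 2)
  expect_equal(hp$end, 9)

  dense <- annotation_track(0:10, letters[1:11], "entry")
  expect_equal(nrow(detect_held_passages(dense, 3)), 0)
  all_gaps <- detect_held_passages(dense, 0)
  expect_equal(nrow(all_gaps), 10)
  expect_true(all(all_gaps$start < all_gaps$end))
  expect_true(all(diff(all_gaps$start) > 0))

  single <- annotation_track(5, "x", "entry")
  expect_equal(nrow(detect_held_passages(single, 1)), 0)
})

test_that("warp maps and feature matrices round-trip through CSV", {
  w <- warp_map(c(0, 1, 2.5), c(0, 1.2, 2.9))
  f <- tempfile(fileext = ".csv")
  write_warp_csv(w, f)
  expect_equal(read_warp_csv(f)$t_a, w$t_a, tolerance = 1e-6)

  set.seed(25)
  feats <- spectro_features(matrix(runif(8 * 40), 8), 0.023)
  ff <- tempfile(fileext = ".csv")
  write_features_csv(feats, ff)
  back <- read_features_csv(ff)
  expect_equal(back$frames, feats$frames, tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(back$hop, 0.023, tolerance = 1e-6)
})
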