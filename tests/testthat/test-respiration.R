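test_that("segmentation recovers ledger onsets on clean traces", {
  expect_equal(nrow(segment_breaths(respiration_trace(rep(1, 300)))), 0)

  p <- quiet_breathing_params(period_range = c(3.5, 3.5), noise_sd = 0,
                              seed = 1)
  qb <- generate_quiet_breathing(p, 35)
  cy <- segment_breaths(qb$trace)
  expect_equal(nrow(cy), 9)   # the 10th cycle has no closing trough
  fs <- qb$trace$sample_rate
  expect_true(all(abs(cy$insp_onset - qb$ledger$insp_onset[1:9]) <= 1 / fs))
  expect_true(all(abs(cy$exp_onset - qb$ledger$exp_onset[1:9]) <= 1 / fs))

  # augmented cycle: count preserved, depth three times the neighbours
  qb2 <- generate_quiet_breathing(
    quiet_breathing_params(noise_sd = 0, seed = 2), 120)
  aug <- inject_disruptions(qb2$trace, qb2$ledger,
                            list(disruption("augmented", 60)))
  cya <- segment_breaths(aug$trace)
  expect_true(abs(nrow(cya) - nrow(aug$ledger)) <= 1)
  i <- which.max(cya$depth)
  expect_equal(cya$depth[i] / stats::median(cya$depth[-i]), 3,
               tolerance = 0.05)
})

test_that("exhaustive extrema scan agrees with segmentation on clean waves", {
  # the two differ only in their tolerance convention at the flat trough
  # floor, which can move an onset by one sample
  for (s in c(3, 9)) {
    qb <- generate_quiet_breathing(
      quiet_breathing_params(noise_sd = 0, seed = s), 90)
    fs <- qb$trace$sample_rate
    cy <- segment_breaths(qb$trace)
    or <- oracle_cycles(qb$trace$values, fs)
    expect_equal(nrow(cy), nrow(or))
    expect_true(all(abs(cy$insp_onset - or$insp_onset) <= 1 / fs + 1e-9))
    expect_true(all(abs(cy$exp_onset - or$exp_onset) <= 1 / fs + 1e-9))
  }
})

test_that("noisy round trip keeps most onsets within three samples", {
  fs <- 26.5
  err <- c()
  for (s in 1:8) {
    qb <- make_quiet(s, 120, noise_sd = 0.05)
    cy <- segment_breaths(qb$trace)
    k <- min(nrow(cy), nrow(qb$ledger))
    err <- c(err,
             abs(cy$insp_onset[1:k] - qb$ledger$insp_onset[1:k]) * fs,
             abs(cy$exp_onset[1:k] - qb$ledger$exp_onset[1:k]) * fs)
  }
  expect_gte(mean(err <= 3), 0.95)
})

test_that("cycle features follow their definitions", {
  p <- quiet_breathing_params(period_range = c(3.5, 3.5), noise_sd = 0,
                              seed = 1)
  qb <- generate_quiet_breathing(p, 70)
  cy <- compute_cycle_features(segment_breaths(qb$trace), qb$trace)
  # onsets quantise to the sample grid, so measured periods wobble by up to
  # one sample (~1.1% of a 3.5 s period)
  expect_true(all(abs(cy$d_period) < 0.025))
  expect_true(all(abs(cy$d_depth) < 0.01))
  expect_true(all(abs(cy$rel_depth - 1) < 0.01))

  # a doubled period gives d_period 1.0 there and 0.5 on the next cycle
  cyc <- concertphys:::breath_cycles_df(
    insp_onset = c(0, 3.5, 7, 14, 17.5),
    exp_onset = c(0, 3.5, 7, 14, 17.5) + 1,
    end = c(3.5, 7, 14, 17.5, 21),
    depth = rep(1, 5))
  tr <- respiration_trace(rep(0, 22 * 26.5), 26.5)
  f <- compute_cycle_features(cyc, tr)
  expect_equal(f$d_period[3], 1.0)
  expect_equal(f$d_period[4], 0.5)
  expect_equal(f$d_depth, rep(0, 5))

  # an augmented breath at 3x the quiet depth has rel_depth 3
  qb2 <- generate_quiet_breathing(
    quiet_breathing_params(noise_sd = 0, seed = 2), 120)
  aug <- inject_disruptions(qb2$trace, qb2$ledger,
                            list(disruption("augmented", 60)))
  fa <- compute_cycle_features(segment_breaths(aug$trace), aug$trace)
  expect_equal(max(fa$rel_depth), 3, tolerance = 0.05)

  other <- respiration_trace(rep(0, 100), 26.5)
  expect_error(compute_cycle_features(cyc, other), "within the trace")
})

test_that("classification implements the quiet-breathing rule set", {
  expect_equal(nrow(classify_breaths(concertphys:::empty_cycles())), 0)

  mk <- function(insp_dur = 1, period = 3.5, rel = 1, dp = 0, dd = 0) {
    cy <- concertphys:::breath_cycles_df(0, insp_dur, period, depth = rel)
    cy$rel_depth <- rel; cy$d_period <- dp; cy$d_depth <- dd
    cy
  }
  th <- classifier_thresholds()
  expect_equal(classify_breaths(mk(), th)$label, "quiet")
  expect_equal(classify_breaths(mk(insp_dur = 0.3), th)$label, "disrupted")
  expect_equal(classify_breaths(mk(period = 7), th)$label, "disrupted")
  expect_equal(classify_breaths(mk(rel = 2.5), th)$label, "disrupted")
  expect_equal(classify_breaths(mk(dp = 0.6), th)$label, "disrupted")
  expect_equal(classify_breaths(mk(dd = 0.7), th)$label, "disrupted")

  r3 <- classify_breaths(mk(rel = 3), th)
  expect_equal(r3$label, "disrupted")
  expect_match(r3$flags, "augmented")

  rapid <- classify_breaths(mk(insp_dur = 0.35), th)
  expect_match(rapid$flags, "rapid_inspiration")

  held <- classify_breaths(mk(period = 8), th)
  expect_match(held$flags, "held")

  # full quiet trace: 100% agreement with the ledger
  qb <- generate_quiet_breathing(quiet_breathing_params(seed = 5), 120)
  cy <- segment_classify(qb$trace)
  expect_true(all(cy$label == "quiet"))
})

test_that("quiet-only traces stay above 99% quiet by time", {
  for (s in c(21, 22, 23)) {
    qb <- make_quiet(s, 120, noise_sd = 0.05)
    cy <- segment_classify(qb$trace)
    expect_gte(quiet_fraction(cy), 0.99)
  }
})

test_that("every injected disruption kind is labelled disrupted", {
  for (s in c(31, 32)) {
    qb <- make_quiet(s, 120, noise_sd = 0.02)
    rb <- inject_disruptions(qb$trace, qb$ledger, list(
      disruption("augmented", 30), disruption("snuck", 60),
      disruption("held", 90)))
    cy <- segment_classify(rb$trace)
    for (i in which(rb$ledger$true_label == "disrupted")) {
      j <- which.min(abs(cy$insp_onset - rb$ledger$insp_onset[i]))
      expect_equal(cy$label[j], "disrupted",
                   label = sprintf("seed %d %s cycle label", s,
                                   rb$ledger$kind[i]))
    }
  }
})

test_that("quiet_fraction weights time or counts as documented", {
  cy <- concertphys:::breath_cycles_df(
    insp_onset = c(0, 3), exp_onset = c(1, 4), end = c(3, 10),
    depth = c(1, 1))
  cy$label <- c("quiet", "disrupted")
  cy$rel_depth <- 1; cy$d_period <- 0; cy$d_depth <- 0
  expect_equal(quiet_fraction(cy, weighting = "time"), 0.3)
  expect_equal(quiet_fraction(cy, weighting = "count"), 0.5)

  allq <- cy; allq$label <- "quiet"
  expect_equal(quiet_fraction(allq), 1.0)

  # invariance under joint time translation
  sh <- cy
  sh$insp_onset <- sh$insp_onset + 100
  sh$exp_onset <- sh$exp_onset + 100
  sh$end <- sh$end + 100
  expect_equal(quiet_fraction(sh, c(100, 110)), quiet_fraction(cy, c(0, 10)))

  expect_error(quiet_fraction(cy, c(50, 60)), "overlaps no")
  un <- cy; un$label <- NA_character_
  expect_error(quiet_fraction(un), "labelled")
})

test_that("phase onsets are ordered and phase-consistent", {
  qb <- generate_quiet_breathing(
    quiet_breathing_params(period_range = c(3.5, 3.5), noise_sd = 0,
                           seed = 1), 35)
  cy <- segment_classify(qb$trace)
  insp <- phase_onsets(cy, "inspiration")
  expo <- phase_onsets(cy, "expiration")
  expect_equal(length(insp), nrow(cy))
  expect_true(all(diff(insp) > 0))
  expect_true(all(expo > insp))
  expect_true(all(abs(insp - qb$ledger$insp_onset[seq_along(insp)])
                  <= 1 / 26.5))
  expect_length(phase_onsets(concertphys:::empty_cycles()), 0)
})

test_that("per-breath tables round-trip through CSV", {
  qb <- make_quiet(41, 60)
  cy <- segment_classify(qb$trace)
  f <- tempfile(fileext = ".csv")
  write_breaths_csv(cy, f)
  back <- read_breaths_csv(f)
  expect_equal(back$insp_onset, cy$insp_onset, tolerance = 1e-9)
  expect_equal(back$label, cy$label)
  expect_equal(back$flags, cy$flags)
})
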