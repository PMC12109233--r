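test_that("quiet breathing generator honours period bounds and determinism", {
  qb <- generate_quiet_breathing(quiet_breathing_params(seed = 1), 60)
  expect_s3_class(qb$trace, "respiration_trace")
  expect_equal(length(qb$trace$values), round(60 * 26.5))
  expect_true(nrow(qb$ledger) >= 15 && nrow(qb$ledger) <= 20)
  expect_true(all(qb$ledger$true_label == "quiet"))
  periods <- qb$ledger$end - qb$ledger$insp_onset
  expect_true(all(periods >= 3 - 1e-9 & periods <= 4 + 1e-9))

  # fixed period, noiseless: exact deterministic construction
  p <- quiet_breathing_params(period_range = c(3.5, 3.5), noise_sd = 0,
                              seed = 1)
  qb2 <- generate_quiet_breathing(p, 35)
  expect_equal(nrow(qb2$ledger), 10)
  expect_equal(qb2$ledger$insp_onset, seq(0, 31.5, by = 3.5))

  # bit-identical reruns with the same seed
  qa <- generate_quiet_breathing(quiet_breathing_params(seed = 7), 60)
  qc <- generate_quiet_breathing(quiet_breathing_params(seed = 7), 60)
  expect_identical(qa$trace$values, qc$trace$values)
  expect_identical(as.data.frame(qa$ledger), as.data.frame(qc$ledger))
  qd <- generate_quiet_breathing(quiet_breathing_params(seed = 8), 60)
  expect_false(identical(qa$trace$values, qd$trace$values))

  expect_error(generate_quiet_breathing(quiet_breathing_params(seed = 1), -5),
               "positive")
  expect_error(generate_quiet_breathing(quiet_breathing_params(seed = 1), 6),
               "twice")
})

test_that("ledger and trace are mutually consistent on noiseless cycles", {
  qb <- generate_quiet_breathing(
    quiet_breathing_params(noise_sd = 0, seed = 4), 80)
  x <- qb$trace$values
  fs <- qb$trace$sample_rate
  for (i in seq_len(nrow(qb$ledger))) {
    lo <- round(qb$ledger$insp_onset[i] * fs) + 1
    hi <- min(round(qb$ledger$end[i] * fs) + 1, length(x))
    peak_t <- (lo - 1 + which.max(x[lo:hi]) - 1) / fs
    expect_lte(abs(peak_t - qb$ledger$exp_onset[i]), 2 / fs)
  }
})

test_that("disruption injection edits exactly the targeted cycles", {
  p <- quiet_breathing_params(noise_sd = 0, seed = 2)
  qb <- generate_quiet_breathing(p, 120)

  # identity on empty specs
  same <- inject_disruptions(qb$trace, qb$ledger, list())
  expect_identical(same$trace$values, qb$trace$values)

  # augmented: one disrupted entry, peak exactly ratio x depth
  aug <- inject_disruptions(qb$trace, qb$ledger,
                            list(disruption("augmented", 50,
                                            depth_ratio = 3)))
  expect_equal(sum(aug$ledger$true_label == "disrupted"), 1)
  # the sample grid can miss the exact peak instant by up to half a sample
  expect_equal(max(aug$trace$values), 3 * p$depth, tolerance = 5e-3)
  i <- which(aug$ledger$true_label == "disrupted")
  expect_equal(aug$ledger$kind[i], "augmented")

  # held: that cycle's period grows by exactly the hold
  held <- inject_disruptions(qb$trace, qb$ledger,
                             list(disruption("held", 50, hold_duration = 5)))
  j <- which(held$ledger$true_label == "disrupted")
  old <- which(qb$ledger$insp_onset <= 50 & qb$ledger$end > 50)
  expect_equal(held$ledger$end[j] - held$ledger$insp_onset[j],
               qb$ledger$end[old] - qb$ledger$insp_onset[old] + 5)

  # snuck: inspiration shorter than half the quiet inspiration
  sn <- inject_disruptions(qb$trace, qb$ledger,
                           list(disruption("snuck", 50)))
  k <- which(sn$ledger$true_label == "disrupted")
  expect_lt(sn$ledger$exp_onset[k] - sn$ledger$insp_onset[k],
            p$insp_duration / 2)

  expect_error(
    inject_disruptions(qb$trace, qb$ledger,
                       list(disruption("augmented", 500))),
    "beyond")
})

test_that("sensor adaptation follows the gain model", {
  qb <- generate_quiet_breathing(
    quiet_breathing_params(noise_sd = 0, seed = 3), 60)

  # no drift, no clipping: identity
  out <- emulate_sensor_adaptation(
    qb$trace, sensor_adaptation_params(slow_gain_rate = 0, clip_level = 10))
  expect_equal(out$values, qb$trace$values, tolerance = 1e-12)

  # clip event halves everything afterwards
  aug <- inject_disruptions(qb$trace, qb$ledger,
                            list(disruption("augmented", 30)))
  ad <- emulate_sensor_adaptation(
    aug$trace, sensor_adaptation_params(slow_gain_rate = 0, clip_level = 1.5,
                                        clip_gain_drop = 0.5))
  expect_true(all(ad$values <= 1.5 + 1e-12))
  i_ev <- min(which(aug$trace$values > 1.5))
  post <- (i_ev + 1):length(ad$values)
  expect_equal(ad$values[post], aug$trace$values[post] * 0.5,
               tolerance = 1e-12)

  # 0.1/min over 10 min roughly doubles the final cycle depth
  long <- generate_quiet_breathing(
    quiet_breathing_params(noise_sd = 0, seed = 5), 600)
  dr <- emulate_sensor_adaptation(
    long$trace, sensor_adaptation_params(slow_gain_rate = 0.1,
                                         clip_level = 100))
  led <- long$ledger
  depth_of <- function(tr, i) {
    fs <- tr$sample_rate
    lo <- round(led$insp_onset[i] * fs) + 1
    hi <- round(led$end[i] * fs)
    max(tr$values[lo:hi])
  }
  ratio <- depth_of(dr, nrow(led)) / depth_of(dr, 1)
  expect_equal(ratio, 2, tolerance = 0.05)
})

test_that("synthetic motion places jolts where requested", {
  still <- generate_motion(20, 256, noise_sd = 0, seed = 1)
  expect_true(all(diff(still$ax) == 0) && all(diff(still$az) == 0))

  m <- generate_motion(30, 256, jolt_times = 10, jolt_magnitude = 2,
                       noise_sd = 0, seed = 1)
  fd <- sqrt(diff(m$ax)^2 + diff(m$ay)^2 + diff(m$az)^2)
  t_max <- (which.max(fd) - 1) / 256
  expect_lt(abs(t_max - 10), 0.2)

  m2 <- generate_motion(30, 256, jolt_times = 10, jolt_magnitude = 2,
                        noise_sd = 0.01, seed = 4)
  m3 <- generate_motion(30, 256, jolt_times = 10, jolt_magnitude = 2,
                        noise_sd = 0.01, seed = 4)
  expect_identical(m2$ax, m3$ax)
})

test_that("performance pair generator matches its tempo curve", {
  ev <- annotation_track(c(5, 12, 20, 28), c("a", "b", "c", "d"), "entry")

  idp <- generate_performance_pair(ev, identity, seed = 1, duration_a = 35)
  expect_equal(idp$track_b$time, ev$time)
  expect_equal(idp$warp$t_b, idp$warp$t_a)
  expect_identical(dim(idp$features_a$frames), dim(idp$features_b$frames))

  dbl <- generate_performance_pair(ev, function(t) 2 * t, seed = 1,
                                   duration_a = 35)
  expect_equal(dbl$track_b$time, 2 * ev$time)

  expect_error(
    generate_performance_pair(ev, function(t) -t, seed = 1, duration_a = 35),
    "increasing")
})

test_that("signal and ledger files round-trip through their readers", {
  qb <- generate_quiet_breathing(quiet_breathing_params(seed = 6), 40)
  f <- tempfile(fileext = ".csv")
  write_respiration_csv(qb$trace, f)
  back <- read_respiration_csv(f)
  expect_equal(back$values, qb$trace$values, tolerance = 1e-5)
  expect_equal(back$sample_rate, 26.5, tolerance = 1e-3)

  lf <- tempfile(fileext = ".csv")
  write_ledger_csv(qb$ledger, lf)
  expect_equal(read_ledger_csv(lf)$insp_onset, qb$ledger$insp_onset,
               tolerance = 1e-6)

  m <- generate_motion(10, 64, jolt_times = 5, seed = 2)
  af <- tempfile(fileext = ".csv")
  write_accel_csv(m, af)
  back_a <- read_accel_csv(af)
  expect_equal(back_a$az, m$az, tolerance = 1e-5)
})
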