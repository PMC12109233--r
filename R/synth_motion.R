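# Synthetic core-body accelerometry: a gravity-like constant on the vertical
# axis, white sensor noise, and brief half-sine jolt transients.

#' Generate synthetic three-axis accelerometry with known jolts
#'
#' Emulates a seated body wearing a chest sensor: near-constant acceleration
#' (gravity on the z axis) plus Gaussian sensor noise, with brief transients
#' ("jolts") of half-sine shape at the requested times, each on a random unit
#' direction in 3-space.
#'
#' @param duration trace duration in seconds.
#' @param sample_rate sampling rate in Hz (nominal 256).
#' @param jolt_times numeric vector of jolt centre times in seconds.
#' @param jolt_magnitude peak acceleration of each jolt, sensor units.
#' @param jolt_width jolt duration in seconds (default 0.08, a brisk limb
#'   movement).
#' @param noise_sd additive noise standard deviation per axis.
#' @param gravity constant vertical acceleration (sensor units).
#' @param seed integer RNG seed.
#' @return an [accel_trace()]; the true jolt times are attached as attribute
#'   `"jolt_times"`.
#' @export
generate_motion <- function(duration, sample_rate = 256,
                            jolt_times = numeric(), jolt_magnitude = 2,
                            jolt_width = 0.08, noise_sd = 0.01,
                            gravity = 9.81, seed = 1L) {
  if (duration <= 0 || sample_rate <= 0)
    stop("`duration` and `sample_rate` must be positive")
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  run_seeded(seed, {
    ax <- stats::rnorm(n, 0, noise_sd)
    ay <- stats::rnorm(n, 0, noise_sd)
    az <- gravity + stats::rnorm(n, 0, noise_sd)
    for (tj in jolt_times) {
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      idx <- which(abs(t - tj) <= jolt_width / 2)
      if (!length(idx)) next
      pulse <- jolt_magnitude * cos(pi * (t[idx] - tj) / jolt_width)^2
      ax[idx] <- ax[idx] + dir[1] * pulse
      ay[idx] <- ay[idx] + dir[2] * pulse
      az[idx] <- az[idx] + dir[3] * pulse
    }
    out <- accel_trace(ax, ay, az, sample_rate)
    attr(out, "jolt_times") <- as.numeric(jolt_times)
    out
  })
}
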