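# Quantity of motion from three-axis accelerometry: downsample to 25 Hz,
# then take the instantaneous jerk magnitude (Euclidean norm of the
# per-axis first difference scaled by the sample rate). Differencing before
# taking the norm makes constant offsets — gravity, posture — vanish.

#' Downsample an acceleration trace
#'
#' Anti-alias low-pass filters each axis (zero-phase Butterworth at 80% of
#' the target Nyquist) and resamples onto a uniform grid at `target_rate` by
#' linear interpolation. Duration is preserved to within one output sample.
#' When `target_rate` equals the source rate the trace is returned
#' unchanged.
#'
#' @param trace an [accel_trace()].
#' @param target_rate output rate in Hz (default 25); must not exceed the
#'   source rate.
#' @return an [accel_trace()] at `target_rate`.
#' @export
resample_accel <- function(trace, target_rate = 25) {
  stopifnot(inherits(trace, "accel_trace"))
  if (target_rate > trace$sample_rate)
    stop("`target_rate` must not exceed the source sample rate")
  if (target_rate == trace$sample_rate) return(trace)
  fs <- trace$sample_rate
  n <- length(trace$ax)
  t_in <- (seq_len(n) - 1) / fs
  n_out <- floor((n - 1) / fs * target_rate) + 1L
  t_out <- (seq_len(n_out) - 1) / target_rate
  bf <- signal::butter(6, (0.8 * target_rate / 2) / (fs / 2))
  res <- lapply(list(trace$ax, trace$ay, trace$az), function(v) {
    # filter around the channel mean: the zero-phase filter's edge
    # transients scale with the DC offset (gravity) otherwise
    mu <- mean(v)
    f <- if (stats::sd(v) == 0) v else signal::filtfilt(bf, v - mu) + mu
    stats::approx(t_in, f, xout = t_out, rule = 2)$y
  })
  out <- accel_trace(res[[1]], res[[2]], res[[3]], target_rate,
                     trace$start_time)
  attr(out, "jolt_times") <- attr(trace, "jolt_times")
  out
}

#' Quantity of motion (jerk magnitude)
#'
#' `value[i] = sqrt(dax[i]^2 + day[i]^2 + daz[i]^2) * sample_rate`, where
#' `da*` are the per-axis first differences; the output has one sample fewer
#' than the input and the same rate. Apply after [resample_accel()] to the
#' conventional 25 Hz.
#'
#' @param trace an [accel_trace()] (typically at 25 Hz).
#' @return a [qom_series()].
#' @export
quantity_of_motion <- function(trace) {
  stopifnot(inherits(trace, "accel_trace"))
  j <- sqrt(diff(trace$ax)^2 + diff(trace$ay)^2 + diff(trace$az)^2) *
    trace$sample_rate
  qom_series(j, trace$sample_rate,
             trace$start_time + 1 / trace$sample_rate)
}

#' Detect discrete movement jolts in a QoM series
#'
#' Local maxima whose robust z-score — relative to the series median and
#' median absolute deviation — exceeds `z_threshold` are reported, greedily
#' thinned so that detections are at least `min_separation` seconds apart
#' (larger magnitudes win).
#'
#' @param qom a [qom_series()].
#' @param z_threshold robust z-score threshold (default 6).
#' @param min_separation minimum time between detections, seconds.
#' @return a data frame with columns `time` and `magnitude`, ordered by
#'   time; zero rows when the series is flat or nothing exceeds the
#'   threshold.
#' @export
detect_jolts <- function(qom, z_threshold = 6, min_separation = 0.5) {
  stopifnot(inherits(qom, "qom_series"), length(qom$values) > 0)
  v <- qom$values
  med <- stats::median(v)
  madv <- stats::mad(v)
  if (madv == 0) {
    # degenerate spread: fall back to any strictly dominant excursion
    if (all(v == med)) return(data.frame(time = numeric(),
                                         magnitude = numeric()))
    madv <- stats::sd(v)
  }
  z <- (v - med) / madv
  n <- length(v)
  is_peak <- z > z_threshold &
    v >= c(-Inf, v[-n]) & v > c(v[-1], -Inf)
  idx <- which(is_peak)
  if (!length(idx)) return(data.frame(time = numeric(),
                                      magnitude = numeric()))
  tt <- trace_times(qom)[idx]
  mag <- v[idx]
  keep <- logical(length(idx))
  for (j in order(mag, decreasing = TRUE)) {
    if (!any(keep & abs(tt - tt[j]) < min_separation)) keep[j] <- TRUE
  }
  out <- data.frame(time = tt[keep], magnitude = mag[keep])
  out[order(out$time), , drop = FALSE]
}

#' Write detected jolts as an annotation file
#'
#' @param jolts the data frame from [detect_jolts()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_jolts <- function(jolts, path) {
  track <- annotation_track(jolts$time,
                            sprintf("jolt_%.3g", jolts$magnitude),
                            "other")
  write_annotations(track, path)
}
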