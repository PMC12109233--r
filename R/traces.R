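#' Respiration trace
#'
#' A uniformly sampled relative chest-stretch wave, as produced by a
#' respiration belt. Values are in arbitrary sensor units (the belt reports
#' relative stretch with adaptive sensitivity, so amplitudes carry no
#' calibrated volume meaning); only phase timing and relative depth are
#' interpretable.
#'
#' @param values numeric vector of chest-stretch samples (finite).
#' @param sample_rate sampling rate in Hz (nominal 26.5 for the vest sensor).
#' @param start_time time of the first sample in seconds.
#' @return an object of class `respiration_trace` with elements `values`,
#'   `sample_rate`, `start_time`.
#' @export
respiration_trace <- function(values, sample_rate = 26.5, start_time = 0) {
  values <- as.numeric(values)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("`sample_rate` must be a single positive number")
  if (anyNA(values) || any(!is.finite(values)))
    stop("`values` must be finite and non-missing")
  structure(
    list(values = values, sample_rate = sample_rate,
         start_time = as.numeric(start_time)),
    class = "respiration_trace")
}

#' @export
print.respiration_trace <- function(x, ...) {
  cat(sprintf("<respiration_trace> %d samples @ %.3g Hz, %.1f s (t0 = %.2f s)\n",
              length(x$values), x$sample_rate,
              length(x$values) / x$sample_rate, x$start_time))
  invisible(x)
}

#' Sample times of a trace
#'
#' @param x a `respiration_trace`, `accel_trace` or `qom_series`.
#' @return numeric vector of sample times in seconds.
#' @export
trace_times <- function(x) {
  n <- if (inherits(x, "accel_trace")) length(x$ax) else length(x$values)
  x$start_time + (seq_len(n) - 1) / x$sample_rate
}

#' Duration of a trace in seconds
#' @param x a trace object.
#' @return duration in seconds (n / sample_rate).
#' @export
trace_duration <- function(x) {
  n <- if (inherits(x, "accel_trace")) length(x$ax) else length(x$values)
  n / x$sample_rate
}

#' @export
plot.respiration_trace <- function(x, ...) {
  plot(trace_times(x), x$values, type = "l", xlab = "time (s)",
       ylab = "chest stretch (a.u.)", ...)
  invisible(x)
}

#' Three-axis acceleration trace
#'
#' Core-body acceleration from a wearable sensor, three channels sampled
#' uniformly (nominal 256 Hz).
#'
#' @param ax,ay,az numeric vectors of equal length, acceleration in sensor
#'   units.
#' @param sample_rate sampling rate in Hz.
#' @param start_time time of the first sample in seconds.
#' @return an object of class `accel_trace`.
#' @export
accel_trace <- function(ax, ay, az, sample_rate = 256, start_time = 0) {
  ax <- as.numeric(ax); ay <- as.numeric(ay); az <- as.numeric(az)
  if (length(ax) != length(ay) || length(ax) != length(az))
    stop("acceleration channels must have equal length")
  if (sample_rate <= 0) stop("`sample_rate` must be positive")
  vals <- c(ax, ay, az)
  if (anyNA(vals) || any(!is.finite(vals)))
    stop("acceleration values must be finite")
  structure(
    list(ax = ax, ay = ay, az = az, sample_rate = as.numeric(sample_rate),
         start_time = as.numeric(start_time)),
    class = "accel_trace")
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> 3 x %d samples @ %.4g Hz, %.1f s\n",
              length(x$ax), x$sample_rate, trace_duration(x)))
  invisible(x)
}

#' Quantity-of-motion series
#'
#' Jerk-magnitude time series (sensor units per second) derived from
#' three-axis acceleration; values are non-negative.
#'
#' @param values numeric vector of jerk magnitudes (>= 0).
#' @param sample_rate sampling rate in Hz (nominal 25).
#' @param start_time time of the first sample in seconds.
#' @return an object of class `qom_series`.
#' @export
qom_series <- function(values, sample_rate = 25, start_time = 0) {
  values <- as.numeric(values)
  if (any(values < 0)) stop("QoM values must be non-negative")
  if (sample_rate <= 0) stop("`sample_rate` must be positive")
  structure(
    list(values = values, sample_rate = as.numeric(sample_rate),
         start_time = as.numeric(start_time)),
    class = "qom_series")
}

#' @export
print.qom_series <- function(x, ...) {
  cat(sprintf("<qom_series> %d samples @ %.3g Hz, peak %.3g\n",
              length(x$values), x$sample_rate,
              if (length(x$values)) max(x$values) else NA_real_))
  invisible(x)
}

#' @export
plot.qom_series <- function(x, ...) {
  plot(trace_times(x), x$values, type = "l", xlab = "time (s)",
       ylab = "jerk magnitude (a.u./s)", ...)
  invisible(x)
}

#' Read / write signal CSV files
#'
#' Signal files are plain CSV with a header: `time_s,value` for univariate
#' signals (respiration, QoM) and `time_s,ax,ay,az` for acceleration. Sampling
#' is assumed uniform; the rate is inferred from the median time step unless
#' given.
#'
#' @param path file path.
#' @param sample_rate optional explicit rate in Hz; inferred from time stamps
#'   when `NULL`.
#' @return `read_respiration_csv` a `respiration_trace`; `read_accel_csv` an
#'   `accel_trace`; `read_qom_csv` a `qom_series`; writers return the path,
#'   invisibly.
#' @name signal_csv
NULL

infer_rate <- function(time_s) {
  dt <- diff(time_s)
  if (length(dt) == 0L || any(dt <= 0)) stop("time stamps must be increasing")
  1 / stats::median(dt)
}

#' @rdname signal_csv
#' @export
read_respiration_csv <- function(path, sample_rate = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(d)))
    stop("expected columns `time_s,value` in ", path)
  if (is.null(sample_rate)) sample_rate <- infer_rate(d$time_s)
  respiration_trace(d$value, sample_rate, start_time = d$time_s[1])
}

#' @rdname signal_csv
#' @param trace the trace to write.
#' @export
write_respiration_csv <- function(trace, path) {
  utils::write.csv(
    data.frame(time_s = round(trace_times(trace), 6),
               value = trace$values),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname signal_csv
#' @export
read_accel_csv <- function(path, sample_rate = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "ax", "ay", "az") %in% names(d)))
    stop("expected columns `time_s,ax,ay,az` in ", path)
  if (is.null(sample_rate)) sample_rate <- infer_rate(d$time_s)
  accel_trace(d$ax, d$ay, d$az, sample_rate, start_time = d$time_s[1])
}

#' @rdname signal_csv
#' @export
write_accel_csv <- function(trace, path) {
  utils::write.csv(
    data.frame(time_s = round(trace_times(trace), 6),
               ax = trace$ax, ay = trace$ay, az = trace$az),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname signal_csv
#' @export
read_qom_csv <- function(path, sample_rate = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(d)))
    stop("expected columns `time_s,value` in ", path)
  if (is.null(sample_rate)) sample_rate <- infer_rate(d$time_s)
  qom_series(d$value, sample_rate, start_time = d$time_s[1])
}

#' @rdname signal_csv
#' @param qom the series to write.
#' @export
write_qom_csv <- function(qom, path) {
  utils::write.csv(
    data.frame(time_s = round(trace_times(qom), 6), value = qom$values),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
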