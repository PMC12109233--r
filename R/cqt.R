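# Constant-Q spectrogram with one bin per semitone. Each bin k has centre
# frequency f_k = f_low * 2^(k/12) and a Hann-windowed complex-exponential
# kernel whose length N_k = Q * sr / f_k keeps the relative bandwidth
# constant (Q = 1 / (2^(1/12) - 1), about 16.8, i.e. one semitone).

note_frequency <- function(note) {
  # scientific pitch notation relative to A4 = 440 Hz
  m <- regmatches(note, regexec("^([A-Ga-g])([#b]?)(-?[0-9]+)$", note))[[1]]
  if (length(m) != 4L) stop("cannot parse note name: ", note)
  base <- c(C = 0, D = 2, E = 4, F = 5, G = 7, A = 9, B = 11)[toupper(m[2])]
  semis <- base + switch(m[3], "#" = 1L, "b" = -1L, 0L)
  midi <- 12L * (as.integer(m[4]) + 1L) + semis
  440 * 2^((midi - 69) / 12)
}

#' Spectrogram-like feature matrix
#'
#' Container shared by the constant-Q transform of real audio and the
#' synthetic per-frame feature vectors of [generate_performance_pair()]:
#' a non-negative matrix with one row per (pitch) bin and one column per
#' frame, frames uniformly `hop` seconds apart.
#'
#' @param frames numeric matrix, bins x frames, non-negative.
#' @param hop frame hop in seconds.
#' @param frame_times frame centre times; defaults to `0, hop, 2*hop, ...`.
#' @param bin_freqs optional bin centre frequencies in Hz.
#' @return an object of class `spectro_features`.
#' @export
spectro_features <- function(frames, hop, frame_times = NULL,
                             bin_freqs = NULL) {
  frames <- as.matrix(frames)
  if (any(frames < 0)) stop("feature energies must be non-negative")
  if (is.null(frame_times))
    frame_times <- (seq_len(ncol(frames)) - 1) * hop
  if (length(frame_times) != ncol(frames))
    stop("`frame_times` must have one entry per frame")
  structure(list(frames = frames, hop = hop,
                 frame_times = as.numeric(frame_times),
                 bin_freqs = bin_freqs),
            class = "spectro_features")
}

#' @export
print.spectro_features <- function(x, ...) {
  cat(sprintf("<spectro_features> %d bins x %d frames, hop %.4g s (%.1f s)\n",
              nrow(x$frames), ncol(x$frames), x$hop,
              if (length(x$frame_times)) max(x$frame_times) else 0))
  invisible(x)
}

#' Constant-Q spectrogram of audio
#'
#' Computes magnitudes (not dB) of a constant-Q transform with one bin per
#' semitone from `low_pitch` to `high_pitch` inclusive, at a frame hop of
#' `hop` seconds. Kernels are Hann-windowed complex exponentials of
#' frequency-dependent length, normalised so a unit-amplitude sinusoid at a
#' bin centre yields magnitude ~0.5 in that bin.
#'
#' @param samples numeric audio samples (mono; downmix first if needed).
#' @param sample_rate audio rate in Hz.
#' @param hop frame hop in seconds (default 0.023).
#' @param low_pitch,high_pitch pitch bounds in scientific notation
#'   (defaults C1 to C7).
#' @return a [spectro_features()] with `bin_freqs` set.
#' @export
cqt_spectrogram <- function(samples, sample_rate, hop = 0.023,
                            low_pitch = "C1", high_pitch = "C7") {
  if (!length(samples)) stop("empty audio")
  if (length(samples) / sample_rate <= 1)
    stop("audio must be longer than 1 s")
  f_lo <- note_frequency(low_pitch)
  f_hi <- note_frequency(high_pitch)
  if (f_hi <= f_lo) stop("`high_pitch` must be above `low_pitch`")
  if (f_hi >= sample_rate / 2)
    stop("`high_pitch` is at or above the Nyquist frequency")
  n_bins <- round(12 * log2(f_hi / f_lo)) + 1L
  freqs <- f_lo * 2^((seq_len(n_bins) - 1) / 12)
  q <- 1 / (2^(1 / 12) - 1)
  n <- length(samples)
  centers <- seq(0, (n - 1) / sample_rate, by = hop)
  frames <- matrix(0, n_bins, length(centers))
  for (k in seq_len(n_bins)) {
    nk <- min(2L * (ceiling(q * sample_rate / freqs[k]) %/% 2L) + 1L, n)
    half <- nk %/% 2L
    rel <- (-half):half
    win <- 0.5 - 0.5 * cos(2 * pi * (rel + half) / (nk - 1L))
    win <- win / sum(win)
    phase <- 2 * pi * freqs[k] * rel / sample_rate
    kr <- win * cos(phase)
    ki <- win * sin(phase)
    ci <- round(centers * sample_rate) + 1L
    for (j in seq_along(ci)) {
      idx <- ci[j] + rel
      keep <- idx >= 1L & idx <= n
      sk <- samples[idx[keep]]
      frames[k, j] <- sqrt(sum(sk * kr[keep])^2 + sum(sk * ki[keep])^2)
    }
  }
  spectro_features(frames, hop, frame_times = centers, bin_freqs = freqs)
}

#' Read / write feature matrices as CSV
#'
#' Frames are rows on disk (`time_s` then one column per bin) so files are
#' long rather than wide.
#'
#' @param feats a [spectro_features()] object.
#' @param path file path.
#' @return the path (writer) or a [spectro_features()] (reader).
#' @export
write_features_csv <- function(feats, path) {
  d <- data.frame(time_s = round(feats$frame_times, 6),
                  t(feats$frames))
  names(d) <- c("time_s", sprintf("bin%02d", seq_len(nrow(feats$frames))))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  d <- utils::read.csv(path)
  if (names(d)[1] != "time_s") stop("expected first column `time_s` in ", path)
  tt <- d$time_s
  hop <- stats::median(diff(tt))
  spectro_features(t(as.matrix(d[, -1, drop = FALSE])), hop,
                   frame_times = tt)
}
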