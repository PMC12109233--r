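# Synthetic pair of performances of the same "work": one shared score
# rendered on two timelines related by a tempo curve, with per-frame feature
# vectors mimicking note onsets (sparse pitch profiles with sharp attacks and
# exponential decay) so that audio-style alignment has real landmarks.

#' Generate a tempo-warped pair of performances with ground truth
#'
#' Takes an annotation track on performance A's timeline and a strictly
#' increasing tempo curve mapping A-time to B-time, and emits: the original
#' track, the warped track, the exact warp map sampled on a frame grid, and a
#' pair of synthetic spectrogram-like feature matrices consistent with both
#' timelines. The features are built from a common "score": dense random
#' note onsets (every 0.2-0.5 s) with sparse non-negative pitch-bin profiles
#' and exponentially decaying envelopes, plus stronger bumps locked to the
#' annotated events.
#'
#' @param events an [annotation_track()] on performance A's timeline.
#' @param tempo_curve a vectorised, strictly increasing function mapping
#'   A-time (seconds) to B-time (seconds) with `tempo_curve(0) ~ 0`.
#' @param seed integer RNG seed.
#' @param duration_a duration of performance A in seconds; defaults to the
#'   last event time plus 5 s.
#' @param hop feature frame hop in seconds (default 0.023, matching the
#'   spectrogram convention used for real audio).
#' @param n_bins number of feature bins (default 36, i.e. three octaves of
#'   semitones).
#' @param noise_sd additive feature noise.
#' @return a list with elements `track_a`, `track_b` (annotation tracks),
#'   `warp` (a [warp_map()] holding the exact correspondence), `features_a`,
#'   `features_b` ([spectro_features()]).
#' @export
generate_performance_pair <- function(events, tempo_curve, seed = 1L,
                                      duration_a = NULL, hop = 0.023,
                                      n_bins = 36, noise_sd = 0.005) {
  stopifnot(inherits(events, "annotation_track"), is.function(tempo_curve))
  if (is.null(duration_a)) {
    if (!nrow(events)) stop("need events or an explicit `duration_a`")
    duration_a <- max(events$time) + 5
  }
  probe <- seq(0, duration_a, by = hop / 2)
  curve_vals <- tempo_curve(probe)
  if (any(diff(curve_vals) <= 0))
    stop("`tempo_curve` must be strictly increasing over the event span")
  duration_b <- tempo_curve(duration_a)

  track_b <- annotation_track(tempo_curve(events$time), events$label,
                              events$kind)

  times_a <- seq(0, duration_a, by = hop)
  times_b <- seq(0, duration_b, by = hop)
  # score time of each B frame: invert the tempo curve numerically
  score_of_b <- stats::approx(curve_vals, probe, xout = times_b,
                              rule = 2)$y
  warp <- warp_map(t_b = tempo_curve(times_a), t_a = times_a)

  run_seeded(seed, {
    gaps <- stats::runif(ceiling(duration_a / 0.2) + 10L, 0.2, 0.5)
    note_times <- cumsum(gaps)
    note_times <- note_times[note_times < duration_a]
    note_times <- c(note_times, events$time)   # events are strong onsets
    strengths <- c(rep(1, length(note_times) - nrow(events)),
                   rep(3, nrow(events)))
    profiles <- matrix(0, n_bins, length(note_times))
    for (k in seq_along(note_times)) {
      bins <- sample.int(n_bins, sample.int(4L, 1L) + 1L)
      profiles[bins, k] <- stats::runif(length(bins), 0.5, 1) * strengths[k]
    }
    # sustained drone layer: orchestral texture is rarely a single decaying
    # note, and the continuous mixture keeps every frame distinguishable
    drone_bins <- sample.int(n_bins, 3L)
    knots <- seq(0, duration_a + 1, by = 1)
    drone_amp <- matrix(stats::runif(3L * length(knots), 0.3, 0.8), 3L)
    render <- function(score_times) {
      fr <- matrix(0, n_bins, length(score_times))
      tau <- 0.2; horizon <- 1.2
      for (k in seq_along(note_times)) {
        idx <- which(score_times >= note_times[k] &
                     score_times < note_times[k] + horizon)
        if (!length(idx)) next
        env <- exp(-(score_times[idx] - note_times[k]) / tau)
        fr[, idx] <- fr[, idx] + profiles[, k] %o% env
      }
      for (d in 1:3) {
        fr[drone_bins[d], ] <- fr[drone_bins[d], ] +
          stats::approx(knots, drone_amp[d, ], xout = score_times,
                        rule = 2)$y
      }
      fr
    }
    fa <- render(times_a)
    fb <- render(score_of_b)
    fa <- fa + matrix(abs(stats::rnorm(length(fa), 0, noise_sd)), n_bins)
    fb <- fb + matrix(abs(stats::rnorm(length(fb), 0, noise_sd)), n_bins)
    list(track_a = events, track_b = track_b, warp = warp,
         features_a = spectro_features(fa, hop, frame_times = times_a),
         features_b = spectro_features(fb, hop, frame_times = times_b))
  })
}
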