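# Breath-cycle segmentation.
#
# A cycle runs trough -> peak -> next trough: inspiration onset at the trough
# that precedes a rise of meaningful prominence, expiration onset at the
# following peak. Candidate extrema are found on a low-pass smoothed copy of
# the wave, micro-oscillations below a prominence floor are merged away, and
# the surviving onsets are refined back onto the raw wave.

# centred moving average with partial windows at the edges (zero phase)
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- (w - 1L) %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# alternating trough/peak indices of a series, flats resolved so that a
# trough is the last sample of a minimal run and a peak the last sample of a
# maximal run (peak position is refined on the raw wave later, where the
# first maximal sample is taken)
alternating_extrema <- function(s) {
  d <- diff(s)
  r <- rle(sign(d))
  troughs <- integer(); peaks <- integer()
  pos <- cumsum(c(1L, r$lengths))   # start index (in d coords) of each run
  last_dir <- 0L
  for (k in seq_along(r$values)) {
    v <- r$values[k]
    if (v == 0) next
    if (v > 0) {
      if (last_dir <= 0) troughs <- c(troughs, pos[k])
      last_dir <- 1L
    } else {
      if (last_dir >= 0) peaks <- c(peaks, pos[k])
      last_dir <- -1L
    }
  }
  list(troughs = troughs, peaks = peaks)
}

# merge peaks whose swing falls below a prominence floor of 10% of the
# running cycle-depth median. Noise micro-oscillations can outnumber true
# cycles, which would drag a plain median down to the noise scale, so the
# floor is bootstrapped from an upper quantile of the candidate swings and
# then refined with the median of the surviving depths. Input and output
# alternate t1 p1 t2 p2 ... (possibly ending with a peak).
prune_extrema <- function(s, troughs, peaks) {
  peaks <- peaks[peaks > if (length(troughs)) troughs[1] else Inf]
  floor_of <- list(
    function(left) 0.1 * stats::quantile(left, 0.95, names = FALSE),
    function(left) 0.1 * stats::median(left))
  for (phase in 1:2) {
    while (length(peaks) && length(troughs) >= 1L) {
      nt <- length(troughs)
      left <- s[peaks] - s[troughs[seq_along(peaks)]]
      right <- rep(Inf, length(peaks))
      has_next <- seq_along(peaks) + 1L <= nt
      right[has_next] <- s[peaks[has_next]] - s[troughs[which(has_next) + 1L]]
      swings <- pmin(left, right)
      bad <- which(swings < floor_of[[phase]](left))
      if (!length(bad)) break
      j <- bad[which.min(swings[bad])]
      if (j + 1L <= nt) {
        drop_tr <- if (s[troughs[j]] >= s[troughs[j + 1L]]) j else j + 1L
        troughs <- troughs[-drop_tr]
      }
      peaks <- peaks[-j]
    }
  }
  list(troughs = troughs, peaks = peaks)
}

# Onset refiners. On a clean wave the trough is the last raw sample at the
# segment minimum and the peak the first raw sample at the maximum — exact
# for synthetic waves with flat pauses. Under white sensor noise the shallow
# foot of the inspiration rise is swamped, so refinement runs on a
# zero-phase low-pass copy: trough = last sample within 2 post-filter noise
# sd of the segment minimum (one sample back for the threshold-crossing
# bias), peak = argmax plus one sample (the filter pulls the peak of the
# slow-rise/fast-decay shape slightly early).
make_refiner <- function(x, fs, sig, noisy, cutoff = 1.2) {
  if (!noisy) {
    tol <- 2 * sig
    return(list(
      trough = function(lo, hi) {
        seg <- x[lo:hi]
        lo - 1L + max(which(seg <= min(seg) + tol))
      },
      peak = function(lo, hi) {
        seg <- x[lo:hi]
        lo - 1L + min(which(seg >= max(seg) - tol))
      }))
  }
  xf <- signal::filtfilt(signal::butter(4, cutoff / (fs / 2)), x)
  tol <- 2 * sig * sqrt(2 * cutoff / fs)
  list(
    trough = function(lo, hi) {
      seg <- xf[lo:hi]
      # baseline from the low quartile: robust to residual noise dips,
      # unlike the raw segment minimum
      base <- stats::median(seg[seg <= stats::quantile(seg, 0.25,
                                                       names = FALSE)])
      max(lo - 1L + max(which(seg <= base + tol)) - 1L, lo)
    },
    peak = function(lo, hi) {
      seg <- xf[lo:hi]
      min(lo - 1L + which.max(seg) + 1L, hi)
    })
}

# robust per-sample noise scale from second differences (zero for smooth
# noiseless waves, ~sd of additive white noise otherwise)
noise_scale <- function(x) {
  if (length(x) < 4L) return(0)
  1.4826 * stats::median(abs(diff(x, differences = 2L))) / sqrt(6)
}

#' Segment a respiration wave into breath cycles
#'
#' Detects inspiration onsets (troughs preceding a prominent rise) and
#' expiration onsets (the subsequent peaks) and returns one row per complete
#' cycle, unlabelled and without derived features (see
#' [compute_cycle_features()] and [classify_breaths()]). Candidate extrema
#' are located on a zero-phase smoothed copy of the wave; swings smaller than
#' 10% of the running median cycle depth are merged away; onset times are
#' then refined on the raw wave (last sample at the trough floor, first
#' sample at the peak ceiling, with a floor/ceiling tolerance of twice the
#' estimated noise scale).
#'
#' A flat or too-short trace yields zero cycles, not an error.
#'
#' @param trace a [respiration_trace()] of at least 5 s.
#' @param smoothing width of the zero-phase smoothing window in seconds.
#' @return a `breath_cycles` data frame with columns `insp_onset`,
#'   `exp_onset`, `end`, `insp_duration`, `exp_duration`, `period`, `depth`
#'   (peak minus preceding trough, raw amplitude units).
#' @export
segment_breaths <- function(trace, smoothing = 0.6) {
  stopifnot(inherits(trace, "respiration_trace"))
  if (trace_duration(trace) < 5)
    stop("trace must be at least 5 s long")
  x <- trace$values
  fs <- trace$sample_rate
  empty <- empty_cycles()
  if (diff(range(x)) == 0) return(empty)
  w <- round(smoothing * fs)
  if (w %% 2L == 0L) w <- w + 1L
  s <- moving_average(x, w)
  ex <- alternating_extrema(s)
  ex <- prune_extrema(s, ex$troughs, ex$peaks)
  peaks_all <- ex$peaks
  # complete cycles need trough -> peak -> trough
  k <- min(length(peaks_all), length(ex$troughs) - 1L)
  if (k < 1L) return(empty)
  sig <- noise_scale(x)
  depth_scale <- stats::median(s[peaks_all[seq_len(k)]] -
                                 s[ex$troughs[seq_len(k)]])
  # onset refinement signal: the raw wave when it is clean (exact trough
  # recovery), a 1.2 Hz zero-phase low-pass when sensor noise would
  # otherwise dominate the shallow foot of the inspiration rise
  noisy <- sig > 0.005 * depth_scale
  refine <- make_refiner(x, fs, sig, noisy, cutoff = 1.2)
  refine_sharp <- NULL   # higher-bandwidth refiner for short, steep cycles
  tr_raw <- integer(k + 1L)
  pk_raw <- integer(k)
  for (i in seq_len(k + 1L)) {
    lo <- if (i == 1L) 1L else pk_raw[i - 1L]
    # search up to the next smoothed peak (the dropped trailing peak, if
    # any, still bounds the final trough's window)
    hi <- if (i <= length(peaks_all)) peaks_all[i] else length(x)
    tr_raw[i] <- refine$trough(lo, hi)
    if (i <= k) {
      p_hi <- max(ex$troughs[i + 1L], tr_raw[i] + 2L)
      pk_raw[i] <- refine$peak(tr_raw[i] + 1L, p_hi)
      # a narrow inspiration is smeared by the 1.2 Hz refinement filter;
      # such cycles are steep enough to re-refine at higher bandwidth
      if (noisy && (pk_raw[i] - tr_raw[i]) / fs < 0.8) {
        if (is.null(refine_sharp))
          refine_sharp <- make_refiner(x, fs, sig, TRUE, cutoff = 4)
        tr_raw[i] <- refine_sharp$trough(lo, hi)
        pk_raw[i] <- refine_sharp$peak(tr_raw[i] + 1L, p_hi)
      }
    }
  }
  # guard monotone ordering after refinement
  ok <- which(diff(tr_raw) > 0 & pk_raw > tr_raw[-length(tr_raw)] &
              pk_raw < tr_raw[-1L])
  if (!length(ok)) return(empty)
  t0 <- trace$start_time
  insp <- t0 + (tr_raw[ok] - 1L) / fs
  expo <- t0 + (pk_raw[ok] - 1L) / fs
  endt <- t0 + (tr_raw[ok + 1L] - 1L) / fs
  depth <- x[pk_raw[ok]] - x[tr_raw[ok]]
  breath_cycles_df(insp, expo, endt, depth)
}

empty_cycles <- function() {
  breath_cycles_df(numeric(), numeric(), numeric(), numeric())
}

breath_cycles_df <- function(insp_onset, exp_onset, end, depth) {
  structure(
    data.frame(insp_onset = insp_onset, exp_onset = exp_onset, end = end,
               insp_duration = exp_onset - insp_onset,
               exp_duration = end - exp_onset,
               period = end - insp_onset,
               depth = depth,
               rel_depth = rep(NA_real_, length(depth)),
               d_period = rep(NA_real_, length(depth)),
               d_depth = rep(NA_real_, length(depth)),
               label = rep(NA_character_, length(depth)),
               flags = rep("", length(depth)),
               stringsAsFactors = FALSE),
    class = c("breath_cycles", "data.frame"))
}

#' @export
print.breath_cycles <- function(x, ...) {
  lab <- if (all(is.na(x$label))) "unlabelled"
         else sprintf("%d quiet / %d disrupted",
                      sum(x$label == "quiet", na.rm = TRUE),
                      sum(x$label == "disrupted", na.rm = TRUE))
  cat(sprintf("<breath_cycles> %d cycles (%s)\n", nrow(x), lab))
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 4, ...)
  if (nrow(x) > 10L) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

#' @export
summary.breath_cycles <- function(object, ...) {
  out <- list(
    n = nrow(object),
    median_period = stats::median(object$period),
    median_depth = stats::median(object$depth),
    n_quiet = sum(object$label == "quiet", na.rm = TRUE),
    n_disrupted = sum(object$label == "disrupted", na.rm = TRUE),
    quiet_fraction_time = if (!all(is.na(object$label)) && nrow(object))
      quiet_fraction(object) else NA_real_)
  class(out) <- "summary.breath_cycles"
  out
}

#' @export
print.summary.breath_cycles <- function(x, ...) {
  cat(sprintf(
    "%d breath cycles; median period %.2f s, median depth %.3g\n",
    x$n, x$median_period, x$median_depth))
  if (!is.na(x$quiet_fraction_time))
    cat(sprintf("quiet %d / disrupted %d; quiet time-fraction %.3f\n",
                x$n_quiet, x$n_disrupted, x$quiet_fraction_time))
  invisible(x)
}
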