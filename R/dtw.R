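# Audio-to-audio alignment of two performances of the same work: dynamic
# time warping over spectrogram features, then piecewise-linear warping of
# arbitrary time stamps through the recovered correspondence.

#' Monotone time correspondence between two performances
#'
#' Ordered pairs `(t_b, t_a)` mapping performance B's timeline onto
#' performance A's; both coordinates are non-decreasing.
#'
#' @param t_b,t_a numeric vectors of equal length, seconds.
#' @return a data frame of class `warp_map`.
#' @export
warp_map <- function(t_b, t_a) {
  t_b <- as.numeric(t_b); t_a <- as.numeric(t_a)
  if (length(t_b) != length(t_a)) stop("`t_b` and `t_a` lengths differ")
  if (!length(t_b)) stop("a warp map needs at least one pair")
  if (is.unsorted(t_b) || is.unsorted(t_a))
    stop("warp map must be non-decreasing in both coordinates")
  structure(data.frame(t_b = t_b, t_a = t_a),
            class = c("warp_map", "data.frame"))
}

#' @export
print.warp_map <- function(x, ...) {
  sl <- if (nrow(x) > 1L)
    (x$t_a[nrow(x)] - x$t_a[1]) / max(x$t_b[nrow(x)] - x$t_b[1], 1e-12)
  else NA_real_
  cat(sprintf(
    "<warp_map> %d pairs, B [%.2f, %.2f] s -> A [%.2f, %.2f] s (mean slope %.3f)\n",
    nrow(x), x$t_b[1], x$t_b[nrow(x)], x$t_a[1], x$t_a[nrow(x)], sl))
  invisible(x)
}

#' @export
plot.warp_map <- function(x, ...) {
  plot(x$t_b, x$t_a, type = "l", xlab = "performance B time (s)",
       ylab = "performance A time (s)", ...)
  abline(0, 1, lty = 3)
  invisible(x)
}

#' Align two performances by dynamic time warping
#'
#' Finds the globally optimal monotone alignment between the frame sequences
#' of two feature matrices under unit steps (diagonal, horizontal, vertical)
#' with both endpoints constrained, and returns it as a [warp_map()] in
#' seconds. Feature magnitudes are log-compressed (`log(1 + x)`) before the
#' distance is taken; with the default cosine metric each frame is then
#' normalised to unit length (an all-zero frame is at distance 1 from
#' everything, so silent stretches tie and the path keeps to the diagonal).
#'
#' @param features_a,features_b [spectro_features()] with equal bin counts;
#'   A is the reference timeline.
#' @param metric `"cosine"` (default) or `"euclidean"`.
#' @param smooth width, in path pairs, of a moving average applied to the
#'   returned correspondence (endpoints pinned). The optimal path is a
#'   staircase of unit steps; averaging over ~0.25 s removes the
#'   quantisation without affecting genuine tempo structure. Set 0 to keep
#'   the raw path.
#' @return a [warp_map()]; the alignment cost is attached as attribute
#'   `"cost"` and the raw frame path as attribute `"path"`.
#' @export
dtw_align <- function(features_a, features_b,
                      metric = c("cosine", "euclidean"), smooth = 11L) {
  metric <- match.arg(metric)
  stopifnot(inherits(features_a, "spectro_features"),
            inherits(features_b, "spectro_features"))
  if (nrow(features_a$frames) != nrow(features_b$frames))
    stop("feature matrices must have the same bin count")
  prep <- function(f) {
    x <- log1p(f$frames)
    if (metric == "cosine") {
      nrm <- sqrt(colSums(x^2))
      nrm[nrm == 0] <- 1    # zero frames stay zero vectors
      x <- sweep(x, 2L, nrm, "/")
    }
    x
  }
  res <- dtw_core(prep(features_a), prep(features_b),
                  if (metric == "cosine") 0L else 1L)
  path <- res$path
  t_b <- features_b$frame_times[path[, 2]]
  t_a <- features_a$frame_times[path[, 1]]
  if (smooth > 1L && length(t_b) > smooth) {
    ends_b <- t_b[c(1L, length(t_b))]
    ends_a <- t_a[c(1L, length(t_a))]
    t_b <- moving_average(t_b, as.integer(smooth))
    t_a <- moving_average(t_a, as.integer(smooth))
    t_b[1L] <- ends_b[1L]; t_b[length(t_b)] <- ends_b[2L]
    t_a[1L] <- ends_a[1L]; t_a[length(t_a)] <- ends_a[2L]
  }
  out <- warp_map(t_b = t_b, t_a = t_a)
  attr(out, "cost") <- res$cost
  attr(out, "path") <- path
  out
}

#' Warp time stamps through a correspondence map
#'
#' Piecewise-linear interpolation of the `(t_b, t_a)` pairs: times on
#' performance B's timeline are mapped into performance A's. Vertical path
#' segments (several `t_a` for one `t_b`) are averaged. Times outside the
#' map's B span are clamped to its ends with a warning.
#'
#' @param map a [warp_map()].
#' @param times numeric times in seconds (B timeline).
#' @return numeric times on the A timeline, order-preserving.
#' @export
warp_times <- function(map, times) {
  stopifnot(inherits(map, "warp_map"))
  if (!length(times)) return(numeric())
  rng <- range(map$t_b)
  if (any(times < rng[1] - 1e-9 | times > rng[2] + 1e-9))
    warning("times outside the warp map span were clamped")
  if (nrow(map) == 1L) return(rep(map$t_a, length(times)))
  stats::approx(map$t_b, map$t_a, xout = pmin(pmax(times, rng[1]), rng[2]),
                ties = mean, rule = 2)$y
}

#' Invert a warp map
#'
#' @param map a [warp_map()].
#' @return the [warp_map()] sending A times to B times (coordinates
#'   swapped).
#' @export
invert_warp <- function(map) {
  warp_map(t_b = map$t_a, t_a = map$t_b)
}

#' Read / write a warp map CSV (`t_B,t_A`)
#'
#' @param map a [warp_map()].
#' @param path file path.
#' @return the path (writer) or a [warp_map()] (reader).
#' @export
write_warp_csv <- function(map, path) {
  d <- data.frame(t_B = round(map$t_b, 6), t_A = round(map$t_a, 6))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_warp_csv
#' @export
read_warp_csv <- function(path) {
  d <- utils::read.csv(path)
  names(d) <- tolower(names(d))
  if (!all(c("t_b", "t_a") %in% names(d)))
    stop("expected columns `t_B,t_A` in ", path)
  warp_map(d$t_b, d$t_a)
}

#' Held passages: intervals without new onsets
#'
#' Returns every maximal inter-onset gap of at least `min_gap` seconds as an
#' interval `(previous onset, next onset)`. Fewer than two events yield an
#' empty result.
#'
#' @param events an [annotation_track()] (time-sorted).
#' @param min_gap minimum gap in seconds.
#' @return a data frame with columns `start`, `end`; intervals are disjoint
#'   and ordered.
#' @export
detect_held_passages <- function(events, min_gap) {
  stopifnot(inherits(events, "annotation_track"), min_gap >= 0)
  if (nrow(events) < 2L)
    return(data.frame(start = numeric(), end = numeric()))
  tt <- events$time
  gaps <- diff(tt)
  idx <- which(gaps >= min_gap)
  data.frame(start = tt[idx], end = tt[idx + 1L])
}
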