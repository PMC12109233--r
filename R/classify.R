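# Per-cycle features and quiet/disrupted classification.
#
# A breath is quiet when its phase durations, relative depth, and change
# from the previous cycle all fall inside configurable thresholds; anything
# else is disrupted. Flags mark the recognisable disruption shapes: an
# augmented breath (>= 3x the reference quiet depth), a rapid "snuck"
# inspiration, and a held breath (over-long cycle dominated by the
# post-inspiratory phase).

#' Classifier thresholds for quiet breathing
#'
#' Default values translate the qualitative description of resting quiet
#' breathing — an active inspiration of about 1 s within periods of about
#' 3-4 s and stable depth — into explicit bands with margin. They are
#' package defaults, not values fitted to any particular recording, and every
#' one of them is configurable.
#'
#' @param insp_duration_range acceptable inspiration duration, seconds.
#' @param period_range acceptable full cycle period, seconds.
#' @param rel_depth_range acceptable depth relative to the running quiet
#'   reference depth.
#' @param max_d_period maximum relative change in period from the previous
#'   cycle.
#' @param max_d_depth maximum relative change in depth from the previous
#'   cycle.
#' @param augmented_ratio relative depth at or above which a breath is
#'   flagged augmented (the conventional bound is 3, "3 or more times" the
#'   quiet depth).
#' @param rapid_insp_max inspiration duration at or below which a breath is
#'   flagged as a rapid (snuck) inspiration, seconds.
#' @return a list of class `classifier_thresholds`.
#' @export
classifier_thresholds <- function(insp_duration_range = c(0.5, 1.8),
                                  period_range = c(2.0, 6.0),
                                  rel_depth_range = c(0.4, 2.0),
                                  max_d_period = 0.5,
                                  max_d_depth = 0.6,
                                  augmented_ratio = 3.0,
                                  rapid_insp_max = 0.4) {
  stopifnot(length(insp_duration_range) == 2L,
            insp_duration_range[1] <= insp_duration_range[2],
            length(period_range) == 2L,
            period_range[1] <= period_range[2],
            length(rel_depth_range) == 2L,
            rel_depth_range[1] <= rel_depth_range[2],
            max_d_period > 0, max_d_depth > 0,
            augmented_ratio >= 1, rapid_insp_max > 0,
            all(c(insp_duration_range, period_range, rel_depth_range) > 0))
  structure(list(insp_duration_range = as.numeric(insp_duration_range),
                 period_range = as.numeric(period_range),
                 rel_depth_range = as.numeric(rel_depth_range),
                 max_d_period = max_d_period, max_d_depth = max_d_depth,
                 augmented_ratio = augmented_ratio,
                 rapid_insp_max = rapid_insp_max),
            class = "classifier_thresholds")
}

#' Fill per-cycle features of segmented breaths
#'
#' Computes, for each cycle: depth relative to a running reference quiet
#' depth (`rel_depth`) and the relative change in period and depth from the
#' previous cycle (`d_period`, `d_depth`; 0 for the first cycle).
#'
#' The reference depth is the median of the depths of the last
#' `reference_window` cycles provisionally accepted as quiet, bootstrapped
#' from the median of the first five cycles. A cycle enters the reference
#' only if its relative depth lies within `accept_range`, so the reference
#' freezes through disrupted stretches and resumes adapting when quiet
#' cycles return.
#'
#' @param cycles a `breath_cycles` frame from [segment_breaths()].
#' @param trace the [respiration_trace()] the cycles were segmented from
#'   (used for a consistency check).
#' @param reference_window number of accepted quiet depths in the running
#'   reference median.
#' @param accept_range relative-depth band within which a cycle's depth is
#'   admitted to the reference.
#' @return the cycles with `rel_depth`, `d_period`, `d_depth` filled.
#' @export
compute_cycle_features <- function(cycles, trace, reference_window = 10L,
                                   accept_range = c(0.4, 2.0)) {
  stopifnot(inherits(cycles, "breath_cycles"),
            inherits(trace, "respiration_trace"))
  n <- nrow(cycles)
  if (!n) return(cycles)
  span <- c(trace$start_time, trace$start_time + trace_duration(trace))
  if (min(cycles$insp_onset) < span[1] - 1e-6 ||
      max(cycles$end) > span[2] + 1e-6)
    stop("cycles do not lie within the trace: were they segmented from it?")
  depth <- cycles$depth
  ref <- stats::median(depth[seq_len(min(5L, n))])
  accepted <- numeric()
  rel <- numeric(n)
  for (i in seq_len(n)) {
    if (length(accepted) >= 3L)
      ref <- stats::median(utils::tail(accepted, reference_window))
    rel[i] <- depth[i] / ref
    if (rel[i] >= accept_range[1] && rel[i] <= accept_range[2])
      accepted <- c(accepted, depth[i])
  }
  cycles$rel_depth <- rel
  cycles$d_period <- c(0, abs(diff(cycles$period)) /
                          cycles$period[-n])
  cycles$d_depth <- c(0, abs(diff(depth)) / depth[-n])
  cycles
}

#' Classify breath cycles as quiet or disrupted
#'
#' A cycle is quiet iff its inspiration duration, period and relative depth
#' fall inside their threshold ranges and its change in period and depth
#' from the previous cycle do not exceed the maxima; otherwise it is
#' disrupted. Disruption shapes are flagged: `augmented` when relative depth
#' reaches `augmented_ratio`; `rapid_inspiration` when the inspiration is no
#' longer than `rapid_insp_max`; `held` when the period exceeds its upper
#' bound and the post-inspiratory phase dominates (at least twice the
#' inspiration duration).
#'
#' @param cycles a `breath_cycles` frame with features filled
#'   (see [compute_cycle_features()]).
#' @param thresholds a [classifier_thresholds()] object.
#' @return the cycles with `label` and `flags` filled (`flags` is a
#'   comma-separated subset of `augmented`, `rapid_inspiration`, `held`).
#' @export
classify_breaths <- function(cycles, thresholds = classifier_thresholds()) {
  stopifnot(inherits(cycles, "breath_cycles"),
            inherits(thresholds, "classifier_thresholds"))
  n <- nrow(cycles)
  if (!n) return(cycles)
  if (anyNA(cycles$rel_depth))
    stop("features missing: run compute_cycle_features() first")
  th <- thresholds
  quiet <- cycles$insp_duration >= th$insp_duration_range[1] &
           cycles$insp_duration <= th$insp_duration_range[2] &
           cycles$period >= th$period_range[1] &
           cycles$period <= th$period_range[2] &
           cycles$rel_depth >= th$rel_depth_range[1] &
           cycles$rel_depth <= th$rel_depth_range[2] &
           cycles$d_period <= th$max_d_period &
           cycles$d_depth <= th$max_d_depth
  cycles$label <- ifelse(quiet, "quiet", "disrupted")
  aug <- cycles$rel_depth >= th$augmented_ratio
  rapid <- cycles$insp_duration <= th$rapid_insp_max
  held <- cycles$period > th$period_range[2] &
          cycles$exp_duration >= 2 * cycles$insp_duration
  cycles$flags <- vapply(seq_len(n), function(i) {
    paste(c("augmented", "rapid_inspiration", "held")[
      c(aug[i], rapid[i], held[i])], collapse = ",")
  }, character(1))
  cycles
}

#' Fraction of an interval spent in quiet breathing
#'
#' With time weighting (the default) this is the summed duration of quiet
#' cycles clipped to the interval, divided by the total cycle-covered
#' duration in the interval, so quiet and disrupted fractions add to 1. With
#' count weighting it is the fraction of overlapping cycles labelled quiet.
#'
#' @param cycles labelled `breath_cycles`.
#' @param interval `c(start, end)` in seconds; defaults to the full span of
#'   the cycles.
#' @param weighting `"time"` or `"count"`.
#' @return a fraction in `[0, 1]`.
#' @export
quiet_fraction <- function(cycles, interval = NULL,
                           weighting = c("time", "count")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(cycles, "breath_cycles"))
  if (anyNA(cycles$label))
    stop("cycles must be labelled: run classify_breaths() first")
  if (is.null(interval))
    interval <- c(min(cycles$insp_onset), max(cycles$end))
  stopifnot(length(interval) == 2L, interval[1] < interval[2])
  ov <- pmax(0, pmin(cycles$end, interval[2]) -
                pmax(cycles$insp_onset, interval[1]))
  if (!any(ov > 0))
    stop("interval overlaps no breath cycle: quiet fraction undefined")
  isq <- cycles$label == "quiet"
  if (weighting == "time") sum(ov[isq]) / sum(ov)
  else mean(isq[ov > 0])
}

#' Phase onset times of labelled cycles
#'
#' @param cycles a `breath_cycles` frame.
#' @param phase `"inspiration"` or `"expiration"`.
#' @param label optional filter: keep only cycles with this label (e.g.
#'   `"quiet"`); `NULL` keeps all.
#' @return strictly increasing onset times in seconds, one per (kept) cycle.
#' @export
phase_onsets <- function(cycles, phase = c("inspiration", "expiration"),
                         label = NULL) {
  phase <- match.arg(phase)
  stopifnot(inherits(cycles, "breath_cycles"))
  if (!is.null(label)) cycles <- cycles[cycles$label %in% label, ]
  if (phase == "inspiration") cycles$insp_onset else cycles$exp_onset
}

#' Read / write per-breath tables
#'
#' The per-breath CSV stores one row per cycle with onsets, features, label
#' and flags, exactly the columns of a `breath_cycles` frame.
#'
#' @param cycles a `breath_cycles` frame.
#' @param path file path.
#' @return the path (writer) or a `breath_cycles` frame (reader).
#' @export
write_breaths_csv <- function(cycles, path) {
  utils::write.csv(as.data.frame(cycles), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_breaths_csv
#' @export
read_breaths_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- breath_cycles_df(d$insp_onset, d$exp_onset, d$end, d$depth)
  for (col in c("rel_depth", "d_period", "d_depth", "label", "flags")) {
    if (col %in% names(d)) out[[col]] <- d[[col]]
  }
  out$flags[is.na(out$flags)] <- ""
  out
}
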