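# Event-phase coincidence: does a train of breath-phase onsets (or motion
# jolts) land near annotated musical events more often than chance? An event
# is a "hit" when at least one onset falls within a tolerance of it; the
# chance level comes from circularly time-shifting the whole onset train,
# which preserves its internal rhythm while breaking any relation to the
# events.

count_event_hits <- function(onsets, event_times, tolerance,
                             directional = FALSE) {
  if (!length(event_times)) return(0L)
  if (!length(onsets)) return(0L)
  onsets <- sort(onsets)
  i <- findInterval(event_times, onsets)
  n <- length(onsets)
  left <- i >= 1L & (event_times - onsets[pmax(i, 1L)]) <= tolerance
  if (directional) return(sum(left))
  right <- i < n & (onsets[pmin(i + 1L, n)] - event_times) <= tolerance
  sum(left | right)
}

new_coincidence_report <- function(n_events, n_onsets, tolerance, hits,
                                   mode, null_mean = NA_real_,
                                   p_value = NA_real_,
                                   n_permutations = NA_integer_,
                                   seed = NA_integer_) {
  structure(list(
    n_events = n_events, n_onsets = n_onsets, tolerance = tolerance,
    hits = hits,
    hit_rate = if (n_events > 0) hits / n_events else NA_real_,
    mode = mode, null_mean = null_mean, p_value = p_value,
    n_permutations = n_permutations, seed = seed),
    class = "coincidence_report")
}

#' @export
print.coincidence_report <- function(x, ...) {
  cat(sprintf("<coincidence_report> %d/%d events hit (tolerance %.3g s, %s)\n",
              x$hits, x$n_events, x$tolerance, x$mode))
  if (!is.na(x$p_value))
    cat(sprintf("permutation null: mean %.2f hits, p = %.4g (%d shifts)\n",
                x$null_mean, x$p_value, x$n_permutations))
  invisible(x)
}

#' Count events coinciding with phase onsets
#'
#' An event is a hit iff at least one onset lies within `tolerance` of it
#' (closed interval; ties at the boundary count). The `"before"` mode
#' restricts hits to onsets at or before the event — the natural reading of
#' an inspiration *preparing* an entry.
#'
#' @param onsets numeric onset times in seconds (breath-phase onsets, motion
#'   jolts, ...).
#' @param events an [annotation_track()] or numeric event times.
#' @param tolerance half-width of the coincidence window, seconds (> 0).
#' @param mode `"symmetric"` (default) or `"before"`.
#' @return a `coincidence_report` (null fields unset; see
#'   [coincidence_null()]).
#' @export
phase_event_coincidence <- function(onsets, events, tolerance = 0.5,
                                    mode = c("symmetric", "before")) {
  mode <- match.arg(mode)
  if (tolerance <= 0) stop("`tolerance` must be positive")
  ev <- if (inherits(events, "annotation_track")) events$time
        else as.numeric(events)
  hits <- count_event_hits(onsets, ev, tolerance, mode == "before")
  new_coincidence_report(length(ev), length(onsets), tolerance, hits, mode)
}

#' Permutation null for event-phase coincidence
#'
#' Builds the chance distribution of hit counts by circularly shifting the
#' onset train: each permutation adds a uniform random offset to all onsets,
#' wrapping at `duration`, and recounts hits. This preserves the internal
#' structure of the onset train (breathing rhythm, jolt clustering) while
#' destroying any relation to the events, making the test conservative.
#' `p = (1 + #\{null hits >= observed\}) / (1 + n_permutations)`.
#'
#' @inheritParams phase_event_coincidence
#' @param n_permutations number of circular shifts (>= 99).
#' @param seed integer RNG seed.
#' @param duration recording duration in seconds (the wrap length); defaults
#'   to the span of onsets and events together.
#' @return a complete `coincidence_report` with `null_mean`, `p_value`,
#'   `n_permutations`, `seed`; the vector of null hit counts is attached as
#'   attribute `"null_hits"`.
#' @export
coincidence_null <- function(onsets, events, tolerance = 0.5,
                             n_permutations = 1000L, seed = 1L,
                             duration = NULL,
                             mode = c("symmetric", "before")) {
  mode <- match.arg(mode)
  if (n_permutations < 99L) stop("`n_permutations` must be at least 99")
  ev <- if (inherits(events, "annotation_track")) events$time
        else as.numeric(events)
  if (is.null(duration)) duration <- max(c(onsets, ev, 0))
  if (!is.numeric(duration) || duration <= 0)
    stop("recording `duration` must be positive")
  onsets <- sort(onsets %% duration)
  obs <- count_event_hits(onsets, ev, tolerance, mode == "before")
  null_hits <- run_seeded(seed, {
    shifts <- stats::runif(n_permutations, 0, duration)
    vapply(shifts, function(s) {
      shifted <- (onsets + s) %% duration
      # rotation keeps the train sorted without a full re-sort
      cut <- findInterval(duration - s, onsets)
      if (cut > 0L && cut < length(onsets))
        shifted <- c(shifted[(cut + 1L):length(onsets)],
                     shifted[seq_len(cut)])
      else shifted <- sort(shifted)
      count_event_hits_sorted(shifted, ev, tolerance, mode == "before")
    }, integer(1))
  })
  out <- new_coincidence_report(
    length(ev), length(onsets), tolerance, obs, mode,
    null_mean = mean(null_hits),
    p_value = (1 + sum(null_hits >= obs)) / (1 + n_permutations),
    n_permutations = as.integer(n_permutations), seed = as.integer(seed))
  attr(out, "null_hits") <- null_hits
  out
}

# as count_event_hits but trusting that `onsets` is already sorted
count_event_hits_sorted <- function(onsets, event_times, tolerance,
                                    directional = FALSE) {
  if (!length(event_times) || !length(onsets)) return(0L)
  i <- findInterval(event_times, onsets)
  n <- length(onsets)
  left <- i >= 1L & (event_times - onsets[pmax(i, 1L)]) <= tolerance
  if (directional) return(sum(left))
  right <- i < n & (onsets[pmin(i + 1L, n)] - event_times) <= tolerance
  sum(left | right)
}

#' Summarise quiet-breathing fractions across a cohort
#'
#' @param fractions a data frame with columns `participant` and `fraction`,
#'   or a named numeric vector of per-participant quiet fractions.
#' @return a list of class `cohort_summary` with the cohort `median` and a
#'   `participants` table annotated with each fraction's deviation from the
#'   median.
#' @export
cohort_summary <- function(fractions) {
  if (is.numeric(fractions) && !is.data.frame(fractions)) {
    fractions <- data.frame(
      participant = if (is.null(names(fractions)))
        as.character(seq_along(fractions)) else names(fractions),
      fraction = as.numeric(fractions), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(fractions),
            all(c("participant", "fraction") %in% names(fractions)))
  if (!nrow(fractions)) stop("need at least one participant")
  med <- stats::median(fractions$fraction)
  fractions$deviation <- fractions$fraction - med
  structure(list(median = med, participants = fractions),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d participants, median quiet fraction %.3f\n",
              nrow(x$participants), x$median))
  print.data.frame(x$participants, digits = 3)
  invisible(x)
}

#' Write a coincidence report as JSON
#'
#' @param report a `coincidence_report`.
#' @param path output path.
#' @param metadata optional named list merged into the output (e.g. the
#'   event category; reports are per category, with no correction across
#'   categories, and say so).
#' @return the path, invisibly.
#' @export
write_coincidence_json <- function(report, path, metadata = list()) {
  x <- unclass(report)
  x$multiple_testing_correction <- "none (reported per event category)"
  x <- c(x, metadata)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
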