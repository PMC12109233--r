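ANNOTATION_KINDS <- c("rehearsal_mark", "entry", "theme_onset", "fanfare",
                      "meter_change", "other")

#' Annotation track of time-stamped musical events
#'
#' Ordered events (rehearsal numbers, instrument entries, theme onsets, ...)
#' with a time in seconds, a label, and a kind. The on-disk format is the
#' tab-separated `time_s<TAB>label` dialect used by annotation layers in
#' common audio-annotation tools; the kind is carried as an optional third
#' column and defaults to `"other"` when absent.
#'
#' @param time numeric event times in seconds, non-decreasing.
#' @param label character labels, non-empty.
#' @param kind event kinds, each one of `"rehearsal_mark"`, `"entry"`,
#'   `"theme_onset"`, `"fanfare"`, `"meter_change"`, `"other"`.
#' @return a data frame of class `annotation_track` with columns `time`,
#'   `label`, `kind`.
#' @export
annotation_track <- function(time, label, kind = "other") {
  time <- as.numeric(time)
  label <- as.character(label)
  kind <- rep_len(as.character(kind), length(time))
  if (length(time) != length(label))
    stop("`time` and `label` must have equal length")
  if (is.unsorted(time)) stop("event times must be non-decreasing")
  if (any(!nzchar(label))) stop("labels must be non-empty")
  bad <- setdiff(unique(kind), ANNOTATION_KINDS)
  if (length(bad))
    stop("unknown event kind(s): ", paste(bad, collapse = ", "))
  structure(
    data.frame(time = time, label = label, kind = kind,
               stringsAsFactors = FALSE),
    class = c("annotation_track", "data.frame"))
}

#' @export
print.annotation_track <- function(x, ...) {
  cat(sprintf("<annotation_track> %d events", nrow(x)))
  if (nrow(x))
    cat(sprintf(" over [%.2f, %.2f] s", min(x$time), max(x$time)))
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

#' Read an annotation file
#'
#' Parses tab-separated lines `time_s<TAB>label[<TAB>kind]`. Blank lines are
#' skipped; a malformed line raises an error naming its line number.
#'
#' @param path file path.
#' @return an [annotation_track()].
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) return(annotation_track(numeric(), character()))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  time <- numeric(length(keep))
  label <- character(length(keep))
  kind <- character(length(keep))
  for (i in seq_along(keep)) {
    p <- parts[[i]]
    t <- suppressWarnings(as.numeric(p[1]))
    if (length(p) < 2L || is.na(t))
      stop(sprintf("malformed annotation line %d in %s: %s",
                   keep[i], path, lines[keep[i]]))
    time[i] <- t
    label[i] <- p[2]
    kind[i] <- if (length(p) >= 3L && nzchar(p[3])) p[3] else "other"
  }
  o <- order(time)
  annotation_track(time[o], label[o], kind[o])
}

#' Write an annotation file
#'
#' @param track an [annotation_track()].
#' @param path output path.
#' @param with_kind include the kind as a third column (default `TRUE`).
#' @return the path, invisibly.
#' @export
write_annotations <- function(track, path, with_kind = TRUE) {
  lines <- if (with_kind) {
    sprintf("%.6f\t%s\t%s", track$time, track$label, track$kind)
  } else {
    sprintf("%.6f\t%s", track$time, track$label)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Breath ledger: ground-truth breath cycles from the generator
#'
#' One row per generated respiratory cycle, with the true phase onsets and the
#' true label. Used as the oracle when testing segmentation and
#' classification.
#'
#' @param insp_onset,exp_onset,end numeric vectors of phase times in seconds;
#'   within each row `insp_onset < exp_onset < end`, rows ordered and
#'   non-overlapping.
#' @param true_label `"quiet"` or `"disrupted"` per cycle.
#' @param kind disruption kind (`NA` for quiet cycles).
#' @return a data frame of class `breath_ledger`.
#' @export
breath_ledger <- function(insp_onset, exp_onset, end,
                          true_label = "quiet", kind = NA_character_) {
  n <- length(insp_onset)
  true_label <- rep_len(true_label, n)
  kind <- rep_len(as.character(kind), n)
  if (n) {
    stopifnot(all(insp_onset < exp_onset), all(exp_onset < end))
    if (n > 1L && any(insp_onset[-1] < end[-n] - 1e-9))
      stop("ledger entries must be non-overlapping and ordered")
  }
  structure(
    data.frame(insp_onset = as.numeric(insp_onset),
               exp_onset = as.numeric(exp_onset),
               end = as.numeric(end),
               true_label = true_label, kind = kind,
               stringsAsFactors = FALSE),
    class = c("breath_ledger", "data.frame"))
}

#' @export
print.breath_ledger <- function(x, ...) {
  cat(sprintf("<breath_ledger> %d cycles (%d quiet, %d disrupted)\n",
              nrow(x), sum(x$true_label == "quiet"),
              sum(x$true_label == "disrupted")))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  invisible(x)
}

#' @rdname breath_ledger
#' @param ledger a `breath_ledger`.
#' @param path file path.
#' @export
write_ledger_csv <- function(ledger, path) {
  utils::write.csv(as.data.frame(ledger), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname breath_ledger
#' @export
read_ledger_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  breath_ledger(d$insp_onset, d$exp_onset, d$end, d$true_label,
                if ("kind" %in% names(d)) d$kind else NA_character_)
}
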