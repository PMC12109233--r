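# End-to-end case-study runs from a declarative YAML config, plus a
# generator that writes a complete synthetic "concert" bundle ready to run.

#' Load a run configuration
#'
#' A run config is a YAML file (or an equivalent named list) with input
#' paths (`respiration`, `acceleration`, `annotations`; optional
#' `respiration_b`, `annotations_b`, and either `features_a`/`features_b`
#' CSVs or `audio_a`/`audio_b` WAVs for the cross-performance warp),
#' optional `thresholds` overriding [classifier_thresholds()] fields,
#' optional `intervals` (list of `{name, start, end}`), a `coincidence`
#' block (`tolerance`, `n_permutations`, `mode`), a `qom` block
#' (`target_rate`, `jolt_z_threshold`, `min_separation`), a `seed`, and an
#' `out_dir`. Relative paths are resolved against the config file's
#' directory.
#'
#' @param config path to a YAML file or a named list.
#' @return a named list of class `run_config`.
#' @export
load_run_config <- function(config) {
  base <- "."
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    base <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(seed = 1L, out_dir = "out",
                   smoothing = 0.6,
                   qom = list(target_rate = 25, jolt_z_threshold = 6,
                              min_separation = 0.5),
                   coincidence = list(tolerance = 0.5,
                                      n_permutations = 1000L,
                                      mode = "symmetric"),
                   intervals = list(list(name = "full")))
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]]) && nm != "intervals")
      config[[nm]] <- utils::modifyList(defaults[[nm]], config[[nm]])
  }
  for (nm in c("respiration", "acceleration", "annotations",
               "respiration_b", "annotations_b", "features_a", "features_b",
               "audio_a", "audio_b")) {
    p <- config[[nm]]
    if (!is.null(p) && !grepl("^/", p)) config[[nm]] <- file.path(base, p)
  }
  config$thresholds <- do.call(classifier_thresholds,
                               as.list(config$thresholds))
  class(config) <- c("run_config", "list")
  config
}

require_input <- function(path, what) {
  if (is.null(path)) stop("config is missing required input: ", what)
  if (!file.exists(path)) stop(what, " file not found: ", path)
  path
}

analyse_respiration <- function(trace, cfg) {
  cycles <- segment_breaths(trace, smoothing = cfg$smoothing)
  cycles <- compute_cycle_features(cycles, trace)
  classify_breaths(cycles, cfg$thresholds)
}

interval_summaries <- function(cycles, cfg) {
  lapply(cfg$intervals, function(iv) {
    interval <- if (is.null(iv$start)) NULL else c(iv$start, iv$end)
    list(name = if (is.null(iv$name)) "interval" else iv$name,
         start = if (is.null(iv$start)) min(cycles$insp_onset) else iv$start,
         end = if (is.null(iv$end)) max(cycles$end) else iv$end,
         quiet_fraction_time = quiet_fraction(cycles, interval, "time"),
         quiet_fraction_count = quiet_fraction(cycles, interval, "count"),
         n_cycles = nrow(cycles))
  })
}

#' Run a full case-study analysis
#'
#' Reads the configured inputs and writes, under `out_dir`: the per-breath
#' table (`breaths.csv`, plus `breaths_b.csv` when a second-performance
#' respiration is given), the QoM series (`qom.csv`) and detected jolts
#' (`jolts.txt`), the cross-performance warp map (`warp.csv`) with warped
#' second-performance annotations (`annotations_b_warped.txt`) and warped
#' breath tables when the feature/audio pair is configured, coincidence
#' reports per event kind (`coincidence_<kind>.json`), and
#' `summary.json` with quiet fractions per interval and the exact
#' thresholds used. The same config and seed always produce byte-identical
#' outputs.
#'
#' @param config a config path or list (see [load_run_config()]).
#' @return the report bundle as a list, invisibly.
#' @export
run_case_study <- function(config) {
  cfg <- load_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outp <- function(f) file.path(cfg$out_dir, f)

  trace <- read_respiration_csv(require_input(cfg$respiration, "respiration"))
  cycles <- analyse_respiration(trace, cfg)
  write_breaths_csv(cycles, outp("breaths.csv"))

  accel <- read_accel_csv(require_input(cfg$acceleration, "acceleration"))
  accel25 <- resample_accel(accel, cfg$qom$target_rate)
  qom <- quantity_of_motion(accel25)
  write_qom_csv(qom, outp("qom.csv"))
  jolts <- detect_jolts(qom, cfg$qom$jolt_z_threshold,
                        cfg$qom$min_separation)
  write_jolts(jolts, outp("jolts.txt"))

  events <- read_annotations(require_input(cfg$annotations, "annotations"))

  warp <- NULL
  warped <- list()
  have_pair <- (!is.null(cfg$features_a) && !is.null(cfg$features_b)) ||
               (!is.null(cfg$audio_a) && !is.null(cfg$audio_b))
  if (have_pair) {
    feats <- if (!is.null(cfg$features_a)) {
      list(a = read_features_csv(require_input(cfg$features_a, "features_a")),
           b = read_features_csv(require_input(cfg$features_b, "features_b")))
    } else {
      wa <- read_wav(require_input(cfg$audio_a, "audio_a"))
      wb <- read_wav(require_input(cfg$audio_b, "audio_b"))
      list(a = cqt_spectrogram(wa$samples, wa$sample_rate),
           b = cqt_spectrogram(wb$samples, wb$sample_rate))
    }
    warp <- dtw_align(feats$a, feats$b)
    write_warp_csv(warp, outp("warp.csv"))
    if (!is.null(cfg$annotations_b)) {
      ann_b <- read_annotations(require_input(cfg$annotations_b,
                                              "annotations_b"))
      warped$annotations_b <- annotation_track(
        warp_times(warp, ann_b$time), ann_b$label, ann_b$kind)
      write_annotations(warped$annotations_b,
                        outp("annotations_b_warped.txt"))
    }
    if (!is.null(cfg$respiration_b)) {
      trace_b <- read_respiration_csv(require_input(cfg$respiration_b,
                                                    "respiration_b"))
      cycles_b <- analyse_respiration(trace_b, cfg)
      write_breaths_csv(cycles_b, outp("breaths_b.csv"))
      wb <- cycles_b
      for (col in c("insp_onset", "exp_onset", "end"))
        wb[[col]] <- warp_times(warp, cycles_b[[col]])
      wb$insp_duration <- wb$exp_onset - wb$insp_onset
      wb$exp_duration <- wb$end - wb$exp_onset
      wb$period <- wb$end - wb$insp_onset
      warped$cycles_b <- wb
      write_breaths_csv(wb, outp("breaths_b_warped.csv"))
    }
  }

  co_cfg <- cfg$coincidence
  insp <- phase_onsets(cycles, "inspiration")
  dur <- trace$start_time + trace_duration(trace)
  kinds <- unique(events$kind)
  reports <- lapply(c(list(all = events$time),
                      stats::setNames(
                        lapply(kinds, function(k) events$time[events$kind == k]),
                        kinds)),
                    function(ev) {
    coincidence_null(insp, ev, tolerance = co_cfg$tolerance,
                     n_permutations = co_cfg$n_permutations,
                     seed = cfg$seed, duration = dur, mode = co_cfg$mode)
  })
  for (nm in names(reports))
    write_coincidence_json(reports[[nm]],
                           outp(sprintf("coincidence_%s.json", nm)),
                           metadata = list(event_category = nm))

  summary <- list(
    seed = cfg$seed,
    thresholds = unclass(cfg$thresholds),
    smoothing_s = cfg$smoothing,
    intervals = interval_summaries(cycles, cfg),
    n_jolts = nrow(jolts),
    warp_computed = have_pair)
  jsonlite::write_json(summary, outp("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(cycles = cycles, qom = qom, jolts = jolts, warp = warp,
                 warped = warped, coincidence = reports, summary = summary))
}

#' Write a complete synthetic concert bundle
#'
#' Emits, under `out_dir`: respiration and acceleration signal CSVs with
#' ground-truth ledgers, annotation tracks for two tempo-warped performances
#' of the same "work", their feature matrices and exact warp map, a
#' second-performance respiration trace, and a `config.yaml` ready for
#' [run_case_study()].
#'
#' @param seed integer seed; the whole bundle is a deterministic function of
#'   it.
#' @param out_dir output directory (created if needed).
#' @param duration concert duration in seconds (default 300).
#' @return the config path, invisibly; the ground-truth objects are
#'   returned as attribute `"truth"`.
#' @export
make_demo_dataset <- function(seed = 42L, out_dir, duration = 300) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2L) != 0L)
    stop("output directory is not writable: ", out_dir)
  outp <- function(f) file.path(out_dir, f)

  # musical events: rehearsal marks about every 30 s, entries and theme
  # onsets between them, one fanfare and one metre change
  events <- run_seeded(seed, {
    marks <- seq(15, duration - 15, by = 30)
    entries <- sort(stats::runif(round(duration / 20), 5, duration - 5))
    themes <- sort(stats::runif(4, 10, duration - 10))
    tt <- c(marks, entries, themes, duration * 0.4, duration * 0.6)
    ll <- c(sprintf("%d", seq_along(marks)),
            sprintf("entry_%02d", seq_along(entries)),
            sprintf("T%d", seq_along(themes)), "fanfare", "3/4")
    kk <- c(rep("rehearsal_mark", length(marks)),
            rep("entry", length(entries)),
            rep("theme_onset", length(themes)),
            "fanfare", "meter_change")
    o <- order(tt)
    annotation_track(tt[o], ll[o], kk[o])
  })

  qb <- generate_quiet_breathing(
    quiet_breathing_params(seed = seed), duration)
  dis <- list(
    disruption("augmented", time = duration * 0.35, depth_ratio = 3),
    disruption("snuck", time = duration * 0.55,
               insp_duration_override = 0.3),
    disruption("held", time = duration * 0.75, hold_duration = 5))
  rb <- inject_disruptions(qb$trace, qb$ledger, dis)
  write_respiration_csv(rb$trace, outp("respiration.csv"))
  write_ledger_csv(rb$ledger, outp("respiration_ledger.csv"))

  qb2 <- generate_quiet_breathing(
    quiet_breathing_params(seed = seed + 1L), duration)
  write_respiration_csv(qb2$trace, outp("respiration_b.csv"))
  write_ledger_csv(qb2$ledger, outp("respiration_b_ledger.csv"))

  jolt_truth <- c(duration * 0.3, duration * 0.62)
  accel <- generate_motion(duration, sample_rate = 256,
                           jolt_times = jolt_truth, jolt_magnitude = 2,
                           noise_sd = 0.01, seed = seed)
  write_accel_csv(accel, outp("acceleration.csv"))

  # second performance: three tempo segments with slopes in [0.85, 1.25]
  slopes <- run_seeded(seed + 2L, stats::runif(3, 0.85, 1.25))
  knots <- c(0, duration / 3, 2 * duration / 3, duration)
  vals <- c(0, cumsum(slopes * diff(knots)))
  curve <- function(t) stats::approx(knots, vals, xout = t, rule = 2)$y
  pair <- generate_performance_pair(events, curve, seed = seed,
                                    duration_a = duration)
  write_annotations(pair$track_a, outp("annotations.txt"))
  write_annotations(pair$track_b, outp("annotations_b.txt"))
  write_features_csv(pair$features_a, outp("features_a.csv"))
  write_features_csv(pair$features_b, outp("features_b.csv"))
  write_warp_csv(pair$warp, outp("warp_truth.csv"))

  cfg <- list(seed = as.integer(seed),
              respiration = "respiration.csv",
              respiration_b = "respiration_b.csv",
              acceleration = "acceleration.csv",
              annotations = "annotations.txt",
              annotations_b = "annotations_b.txt",
              features_a = "features_a.csv",
              features_b = "features_b.csv",
              out_dir = file.path(out_dir, "out"))
  yaml::write_yaml(cfg, outp("config.yaml"))
  out <- outp("config.yaml")
  attr(out, "truth") <- list(ledger = rb$ledger, ledger_b = qb2$ledger,
                             jolt_times = jolt_truth, warp = pair$warp,
                             events = events)
  invisible(out)
}
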