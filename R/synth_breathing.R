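# Synthetic respiration with a ground-truth ledger.
#
# Quiet breathing is modelled per cycle as: an active inspiration (raised
# cosine from baseline to `depth` over `insp_duration`), optional breath-hold
# plateau, elastic expiration (exponential decay with time constant
# `expiration_decay`, linearly corrected so it lands exactly on baseline), and
# a flat end-of-cycle pause. Baseline is 0 in arbitrary belt units.

run_seeded <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  })
  set.seed(seed)
  force(code)
}

#' Quiet-breathing generator parameters
#'
#' Defaults reflect resting respiration of a seated adult: a ~1 s active
#' inspiration and full respiratory periods of 3-4 s, with stable depth.
#'
#' @param insp_duration active inspiration duration in seconds.
#' @param period_range length-2 range of full cycle periods in seconds;
#'   each cycle's period is drawn uniformly from it.
#' @param depth breath depth in amplitude units (peak minus baseline).
#' @param expiration_decay elastic-relaxation time constant of expiration,
#'   seconds.
#' @param pause_fraction fraction of each period spent at stable baseline
#'   after expiration completes.
#' @param noise_sd additive Gaussian sensor noise, amplitude units.
#' @param seed integer RNG seed.
#' @return a list of class `quiet_breathing_params`.
#' @export
quiet_breathing_params <- function(insp_duration = 1.0,
                                   period_range = c(3.0, 4.0),
                                   depth = 1.0,
                                   expiration_decay = 0.45,
                                   pause_fraction = 0.12,
                                   noise_sd = 0.02,
                                   seed = 1L) {
  stopifnot(insp_duration > 0,
            length(period_range) == 2L,
            period_range[1] <= period_range[2],
            insp_duration < period_range[1],
            depth > 0, expiration_decay > 0,
            pause_fraction >= 0, pause_fraction < 0.5,
            noise_sd >= 0)
  structure(list(insp_duration = insp_duration,
                 period_range = as.numeric(period_range),
                 depth = depth, expiration_decay = expiration_decay,
                 pause_fraction = pause_fraction, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "quiet_breathing_params")
}

# Render a cycle plan (one row per cycle: onset, insp, hold, expd, pause,
# depth) onto a uniform sample grid. Segment boundaries are in seconds from
# cycle onset; baseline is 0.
render_plan <- function(plan, n, sample_rate, tau) {
  values <- numeric(n)
  t <- (seq_len(n) - 1) / sample_rate
  for (k in seq_len(nrow(plan))) {
    o <- plan$onset[k]
    ti <- plan$insp[k]; h <- plan$hold[k]
    te <- plan$expd[k]
    d <- plan$depth[k]
    i0 <- which(t >= o - 1e-9 & t < o + ti + h + te - 1e-9)
    if (!length(i0)) next
    s <- t[i0] - o
    v <- numeric(length(s))
    ins <- s < ti
    v[ins] <- d * (1 - cos(pi * s[ins] / ti)) / 2
    hld <- s >= ti & s < ti + h
    v[hld] <- d
    ex <- s >= ti + h
    se <- s[ex] - ti - h
    # exponential decay with a linear correction so v(te) = 0 exactly
    v[ex] <- d * (exp(-se / tau) - (se / te) * exp(-te / tau))
    values[i0] <- v
  }
  values
}

plan_to_ledger <- function(plan) {
  if (!nrow(plan)) {
    return(breath_ledger(numeric(), numeric(), numeric(),
                         character(), character()))
  }
  breath_ledger(plan$onset, plan$onset + plan$insp,
                plan$onset + plan$insp + plan$hold + plan$expd + plan$pause,
                plan$label, plan$kind)
}

finish_trace <- function(plan, params, n, sample_rate, noise) {
  period <- plan$insp + plan$hold + plan$expd + plan$pause
  end <- plan$onset + period
  duration <- n / sample_rate
  complete <- end <= duration + 1e-9
  clean <- render_plan(plan, n, sample_rate, params$expiration_decay)
  trace <- respiration_trace(clean + noise, sample_rate)
  attr(trace, "plan") <- plan
  attr(trace, "gen_params") <- params
  attr(trace, "gen_noise") <- noise
  list(trace = trace, ledger = plan_to_ledger(plan[complete, , drop = FALSE]))
}

#' Generate a quiet-breathing respiration trace with ground truth
#'
#' Produces a synthetic chest-stretch wave of stable quiet breathing together
#' with a [breath_ledger()] giving the true inspiration onset, expiration
#' onset and cycle end of every complete cycle. Cycle periods are drawn
#' uniformly from `params$period_range` with a seeded generator, so the same
#' seed reproduces the trace bit for bit.
#'
#' @param params a [quiet_breathing_params()] object.
#' @param duration trace duration in seconds; must exceed twice the longest
#'   period.
#' @param sample_rate sampling rate in Hz (the belt's nominal rate is 26.5).
#' @return a list with elements `trace` ([respiration_trace()]) and `ledger`
#'   ([breath_ledger()], all cycles labelled quiet).
#' @examples
#' qb <- generate_quiet_breathing(quiet_breathing_params(seed = 7), 60)
#' qb$ledger
#' @export
generate_quiet_breathing <- function(params = quiet_breathing_params(),
                                     duration, sample_rate = 26.5) {
  if (!is.numeric(duration) || duration <= 0 || sample_rate <= 0)
    stop("`duration` and `sample_rate` must be positive")
  if (duration <= 2 * params$period_range[2])
    stop("`duration` must exceed twice the longest period")
  n <- round(duration * sample_rate)
  run_seeded(params$seed, {
    onsets <- numeric(); periods <- numeric()
    t0 <- 0
    repeat {
      # breathing continues past the recording end: the final cycle is
      # rendered partially and excluded from the ledger
      if (t0 >= duration - 1e-9) break
      p <- stats::runif(1, params$period_range[1], params$period_range[2])
      onsets <- c(onsets, t0); periods <- c(periods, p)
      t0 <- t0 + p
    }
    pause <- params$pause_fraction * periods
    expd <- periods - params$insp_duration - pause
    plan <- data.frame(onset = onsets, insp = params$insp_duration,
                       hold = 0, expd = expd, pause = pause,
                       depth = params$depth, label = "quiet",
                       kind = NA_character_, stringsAsFactors = FALSE)
    noise <- if (params$noise_sd > 0) stats::rnorm(n, 0, params$noise_sd)
             else numeric(n)
    finish_trace(plan, params, n, sample_rate, noise)
  })
}

#' Describe one breathing disruption to inject
#'
#' @param kind one of `"augmented"` (a spontaneous deep breath, at least 3x
#'   quiet depth), `"snuck"` (an unusually rapid inspiration squeezed into a
#'   brief gap), `"held"` (breath held at full inspiration), or
#'   `"phase_shift"` (the next inspiration delayed by an extended baseline
#'   pause).
#' @param time time in seconds locating the cycle to disrupt.
#' @param depth_ratio peak depth relative to quiet depth (augmented; the
#'   convention for a spontaneous augmented breath is >= 3).
#' @param insp_duration_override inspiration duration in seconds (snuck;
#'   should be well under half the quiet inspiration).
#' @param hold_duration seconds of breath hold (held) or of added pause
#'   (phase_shift).
#' @return a list of class `disruption_spec` carrying only the fields
#'   relevant to `kind`.
#' @export
disruption <- function(kind = c("augmented", "snuck", "held", "phase_shift"),
                       time, depth_ratio = 3, insp_duration_override = 0.3,
                       hold_duration = 5) {
  kind <- match.arg(kind)
  stopifnot(time >= 0, depth_ratio > 0, insp_duration_override > 0,
            hold_duration > 0)
  out <- list(kind = kind, time = as.numeric(time))
  out <- switch(kind,
    augmented   = c(out, list(depth_ratio = depth_ratio)),
    snuck       = c(out, list(insp_duration_override = insp_duration_override)),
    held        = c(out, list(hold_duration = hold_duration)),
    phase_shift = c(out, list(hold_duration = hold_duration)))
  structure(out, class = "disruption_spec")
}

#' Inject breathing disruptions into a generated trace
#'
#' Rewrites the generator's cycle plan and re-renders the wave, keeping the
#' original noise realisation, so the only changes are the requested
#' disruptions. Augmented breaths scale the cycle's depth; snuck breaths
#' shorten its inspiration; held breaths insert a plateau at full inspiration
#' (extending the cycle and shifting all later cycles); phase shifts extend
#' the baseline pause likewise. Affected cycles are marked disrupted in the
#' returned ledger. Specs are applied in time order; a later spec on the same
#' cycle overrides an earlier one.
#'
#' @param trace a [respiration_trace()] produced by
#'   [generate_quiet_breathing()] (it carries the cycle plan).
#' @param ledger the matching [breath_ledger()] (unused except for interface
#'   symmetry; the plan is authoritative).
#' @param specs a list of [disruption()] objects (possibly empty).
#' @return a list with the re-rendered `trace` and updated `ledger`.
#' @export
inject_disruptions <- function(trace, ledger, specs) {
  plan <- attr(trace, "plan")
  params <- attr(trace, "gen_params")
  noise <- attr(trace, "gen_noise")
  if (is.null(plan) || is.null(params))
    stop("`trace` must come from generate_quiet_breathing()")
  if (!length(specs)) return(list(trace = trace, ledger = ledger))
  if (inherits(specs, "disruption_spec")) specs <- list(specs)
  duration <- trace_duration(trace)
  times <- vapply(specs, `[[`, numeric(1), "time")
  if (any(times >= duration))
    stop("disruption time beyond trace duration")
  for (sp in specs[order(times)]) {
    period <- plan$insp + plan$hold + plan$expd + plan$pause
    end <- plan$onset + period
    i <- which(plan$onset <= sp$time + 1e-9 & sp$time < end)[1]
    if (is.na(i)) stop("no cycle contains disruption time ", sp$time)
    shift <- 0
    if (sp$kind == "augmented") {
      plan$depth[i] <- sp$depth_ratio * params$depth
    } else if (sp$kind == "snuck") {
      plan$insp[i] <- sp$insp_duration_override
      # keep the cycle period: the freed time extends the pause
      plan$pause[i] <- plan$pause[i] +
        (params$insp_duration - sp$insp_duration_override)
    } else if (sp$kind == "held") {
      plan$hold[i] <- plan$hold[i] + sp$hold_duration
      shift <- sp$hold_duration
    } else if (sp$kind == "phase_shift") {
      plan$pause[i] <- plan$pause[i] + sp$hold_duration
      shift <- sp$hold_duration
    }
    if (shift > 0 && i < nrow(plan)) {
      later <- (i + 1L):nrow(plan)
      plan$onset[later] <- plan$onset[later] + shift
    }
    plan$label[i] <- "disrupted"
    plan$kind[i] <- sp$kind
  }
  # drop cycles pushed entirely past the end of the grid
  plan <- plan[plan$onset < duration - 1e-9, , drop = FALSE]
  finish_trace(plan, params, length(trace$values), trace$sample_rate, noise)
}

#' Sensor-adaptation parameters
#'
#' The belt reports stretch with adaptive sensitivity: gain drifts up slowly
#' over minutes, and drops abruptly when an extreme breath clips the range.
#'
#' @param slow_gain_rate relative gain increase per minute (linear in time;
#'   0 disables drift).
#' @param clip_level amplitude at which the sensor clips.
#' @param clip_gain_drop multiplier (in `(0, 1]`) applied to the gain within
#'   one sample of a clipping event.
#' @param recovery `"slow"` (gain keeps drifting up after a drop) or
#'   `"none"` (drift stops after the first clip).
#' @return a list of class `sensor_adaptation_params`.
#' @export
sensor_adaptation_params <- function(slow_gain_rate = 0, clip_level = 2.5,
                                     clip_gain_drop = 0.5,
                                     recovery = c("slow", "none")) {
  recovery <- match.arg(recovery)
  stopifnot(slow_gain_rate >= 0, clip_level > 0,
            clip_gain_drop > 0, clip_gain_drop <= 1)
  structure(list(slow_gain_rate = slow_gain_rate, clip_level = clip_level,
                 clip_gain_drop = clip_gain_drop, recovery = recovery),
            class = "sensor_adaptation_params")
}

#' Apply adaptive sensor gain to a respiration trace
#'
#' Multiplies the wave by a time-varying gain: gain starts at 1 and rises
#' linearly at `slow_gain_rate` per minute; whenever the scaled signal
#' exceeds `clip_level` the gain is multiplied by `clip_gain_drop` within one
#' sample (the triggering sample itself is clamped to `clip_level`).
#'
#' @param trace a [respiration_trace()].
#' @param params a [sensor_adaptation_params()] object.
#' @return a new [respiration_trace()] with adapted amplitudes.
#' @export
emulate_sensor_adaptation <- function(trace, params) {
  stopifnot(inherits(params, "sensor_adaptation_params"))
  v <- trace$values
  inc <- params$slow_gain_rate / 60 / trace$sample_rate
  g <- 1
  growing <- TRUE
  out <- numeric(length(v))
  for (i in seq_along(v)) {
    if (growing) g <- g + inc
    y <- v[i] * g
    if (y > params$clip_level) {
      g <- g * params$clip_gain_drop
      y <- min(v[i] * g, params$clip_level)
      if (params$recovery == "none") growing <- FALSE
    }
    out[i] <- y
  }
  respiration_trace(out, trace$sample_rate, trace$start_time)
}
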