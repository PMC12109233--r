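---
title: "Breath, motion, and musical time: methods behind concertphys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breath, motion, and musical time: methods behind concertphys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concertphys)
```

## What the package measures

Seated audience members at a concert mostly breathe *quietly*: a short
active inspiration of about one second, elastic expiration back to a stable
lung volume, a brief pause, and a full respiratory period of roughly 3–4
seconds. This resting mode is fragile — a spontaneous augmented breath (a
deep sigh of at least three times the quiet depth), a rapid "snuck"
inspiration squeezed between phrases, or a long held breath all break the
pattern, and such disruptions can carry information about how a listener is
engaging with the music. `concertphys` turns four measurement problems into
tested code:

1. **Respiration**: segment a chest-belt stretch wave (nominally 26.5 Hz,
   arbitrary units) into breath cycles, extract per-cycle features, and
   label each cycle quiet or disrupted.
2. **Motion**: reduce three-axis core-body accelerometry (nominally 256 Hz)
   to a quantity-of-motion (QoM) series — the magnitude of jerk after
   downsampling to 25 Hz — and detect discrete jolts.
3. **Alignment**: align two performances of the same work by dynamic time
   warping (DTW) over constant-Q spectrogram features, so signals and
   annotations from a second performance can be read on the first one's
   timeline.
4. **Coincidence**: ask whether breath-phase onsets (or jolts) fall near
   annotated musical events more often than chance, using a circular-shift
   permutation null.

A synthetic-data module generates all of these inputs with ground-truth
ledgers, which is how every stage is validated without concert recordings.

## The respiration model and its segmentation

### Generator

Each synthetic cycle is rendered as a raised-cosine inspiration from
baseline to `depth` over `insp_duration` (default 1 s), an optional plateau
(held breaths), an exponential expiration with time constant
`expiration_decay` (default 0.45 s) corrected linearly so it reaches the
baseline exactly, and a flat pause (`pause_fraction`, default 12% of the
period). Periods are drawn uniformly from `period_range` (default 3–4 s).
The description in the physiology literature is qualitative — an active
shallow inspiration, elastic expiration, a short pause — and the
raised-cosine/exponential pair is this package's concrete reading of it: it
matches the asymmetry (slow smooth rise, fast decay) and gives unambiguous
phase onsets for testing. Breathing continues past the end of the trace
(the final partial cycle is rendered but not entered in the ledger), since
a wave that stops dead at the last complete cycle is both unrealistic and a
segmentation trap.

Additive white Gaussian noise (default sd 0.02 of a unit depth) stands in
for sensor noise. The belt's true noise spectrum is not documented, so this
is a stand-in, not a sensor emulation; the round-trip tests quantify
behaviour at sd 0.02 and 0.05.

Disruptions are injected by editing the cycle plan and re-rendering with
the same noise realisation: `augmented` scales a cycle's depth (default
ratio 3), `snuck` shortens its inspiration (default 0.3 s, with the freed
time added to the pause so the period is preserved), `held` inserts a
plateau at full inspiration and shifts all later cycles, and `phase_shift`
(named but not specified in the source material; defined here) extends the
baseline pause the same way. Sensor adaptation is modelled as a gain that
grows *linearly* at `slow_gain_rate` per minute — linear because a stated
rate of 0.1/min over 10 minutes is expected to double the range — and drops
multiplicatively within one sample when the scaled signal clips.

### Segmentation

`segment_breaths()` works in three stages:

* **Candidates** on a zero-phase moving average (0.6 s window): alternating
  troughs and peaks, with flats resolved to the last minimal / first
  maximal sample.
* **Prominence pruning**: swings below 10% of the running median cycle
  depth are merged away. Because noise micro-oscillations can outnumber
  true cycles, the floor is bootstrapped from the 95th percentile of
  candidate swings before the median takes over; a plain median of all
  candidate swings would itself sit at the noise scale.
* **Refinement** on the raw wave. When the estimated noise scale (from
  second differences, which vanish for smooth waves) is below 0.5% of the
  cycle depth, the trough is the last raw sample at the segment minimum
  and the peak the first raw sample at the maximum — exact to one sample
  on clean waves, including the flat-pause and held-plateau cases. Above
  that, refinement runs on a 1.2 Hz zero-phase Butterworth copy: the foot
  of a raised-cosine rise grows only quadratically, so against white noise
  it is intrinsically poorly localised unless the noise band is cut first.
  The trough is the last sample within twice the post-filter noise sd of a
  low-quartile baseline (a plain minimum would chase noise dips), stepped
  back one sample for the threshold-crossing bias; the peak is the filtered
  argmax plus one sample. Cycles whose first-pass inspiration looks shorter
  than 0.8 s are re-refined at 4 Hz, because a 1.2 Hz filter smears a 0.3 s
  snuck inspiration into an apparently normal one, and steep rises tolerate
  the wider band.

On noiseless fixtures every onset lands within one sample of the generator
ledger; at noise sd = 5% of depth, better than 95% of onsets land within
three samples (about 113 ms). These are the properties the test suite
asserts.

### Features and classification

Per cycle: inspiration duration, period, depth (peak minus preceding
trough), depth relative to a running reference (`rel_depth`), and the
relative change in period and depth from the previous cycle (`d_period`,
`d_depth`, zero for the first cycle). The reference depth is the median of
the last 10 depths provisionally accepted as quiet (accepted when
`rel_depth` is within 0.4–2.0), bootstrapped from the median of the first
five cycles; it therefore freezes through disrupted stretches and resumes
adapting when quiet breathing returns. Whether the reference should adapt
inside disrupted stretches is genuinely open; freezing is the conservative
choice.

A cycle is **quiet** iff all of: inspiration duration in [0.5, 1.8] s,
period in [2, 6] s, `rel_depth` in [0.4, 2.0], `d_period` ≤ 0.5 and
`d_depth` ≤ 0.6. Everything else is **disrupted**. Flags:
`augmented` at `rel_depth ≥ 3` (the "3 or more times" convention — exactly
3.0 is flagged, 2.9 is not), `rapid_inspiration` at inspiration ≤ 0.4 s,
`held` when the period exceeds 6 s and the post-inspiratory phase is at
least twice the inspiration. All bands are package defaults translated from
the qualitative description of quiet breathing, exposed in
`classifier_thresholds()`; they are not fitted to any particular recording.
Note that because `d_period`/`d_depth` compare against the immediately
previous cycle, the quiet cycle *after* a large disruption can itself be
labelled disrupted; this is the stated feature definition, not a defect,
and the tests allow for it.

Quiet percentages are time-weighted by default (summed quiet-cycle duration
over cycle-covered duration) with count weighting as an option, since
reported percentages of a piece are most naturally fractions of its
duration; both are computed by `quiet_fraction()`.

## Quantity of motion

`resample_accel()` low-passes each axis with a zero-phase order-6
Butterworth at 80% of the target Nyquist (filtering around the channel mean
— edge transients otherwise scale with the gravity offset) and linearly
interpolates onto the 25 Hz grid. `quantity_of_motion()` is the Euclidean
norm of the per-axis first difference times the rate: difference-then-norm,
so constant posture/gravity offsets vanish exactly and the series scales
linearly with the acceleration. `detect_jolts()` reports local maxima whose
robust z-score (median/MAD) exceeds 6, thinned greedily to a 0.5 s minimum
separation; the source analyses identified jolts visually, so the detector
is this package's addition and its defaults are deliberately conservative.
Whether to smooth QoM before plotting is left off by default.

## Cross-performance alignment

Features are constant-Q magnitudes with one bin per semitone, C1–C7 by
default (one source passage says C1–C7, a figure caption C1–C8; the ceiling
is configurable), hop 23 ms, Hann-windowed kernels with Q ≈ 16.8.
DTW runs on log-compressed (`log(1+x)`) frames under cosine distance with
unit steps {(1,0),(0,1),(1,1)}, endpoints pinned, no global band
(performances of one work are near-length-matched); the metric and
compression are package choices, as the source names none. The compiled
core keeps two cost rows and a byte traceback, so an 8-minute pair
(~21k × 21k frames) aligns in under a minute within ~0.5 GB. The optimal
path is a staircase of unit steps, so the returned correspondence is
smoothed with a ~0.25 s moving average (endpoints pinned) before
interpolation; `warp_times()` then maps any time stamps — event
annotations, breath onsets, QoM sample times — piecewise-linearly into the
reference timeline. Signals are warped by transforming their time stamps,
never resampled, which preserves breath morphology.

The synthetic performance pair renders a common "score" — dense note onsets
(0.2–0.5 s apart) with sparse pitch profiles and exponential decays, plus
stronger event-locked onsets — on two timelines related by the tempo curve.
A sustained three-bin drone layer with slowly varying amplitude is included
deliberately: under cosine distance a lone decaying note has a constant
direction, which lets the path slide; real orchestral texture is sustained,
and the drone restores the continuous variation that localises the
alignment. With piecewise-linear tempo curves of slopes 0.8–1.3 the
recovered map stays within 2 hops of the generated truth.

## Coincidence against a permutation null

An annotated event is a *hit* when at least one onset lies within a
tolerance (default 0.5 s, closed interval; a `"before"` mode accepts only
onsets at or before the event, matching the reading of an inspiration as
preparation for an entry). Informal arguments that such alignments are
"unlikely coincidence" are formalised as a circular-shift permutation test:
all onsets are shifted by a uniform random offset modulo the recording
duration, preserving the train's internal rhythm while breaking its
relation to the events, and `p = (1 + #{null hits ≥ observed}) /
(1 + permutations)`. The test is exact but conservative and, with a few
dozen events, discrete; calibration checks therefore use dense annotation
tracks (60 events over 10 minutes, typical of a fully annotated orchestral
movement) where the hit-count granularity is small. With onsets generated
independently of events, 200 replicate p-values at 1000 permutations stay
within a Kolmogorov–Smirnov distance of 0.15 from uniform; onsets planted
exactly on 30 sparse events give p ≤ 0.01. No correction across event
categories is applied — reports are per category and say so in their
metadata. `cohort_summary()` implements the median-and-deviation comparison
used to place one participant against the rest of an audience.

## Problem sizes and determinism

Every stochastic step takes an explicit integer seed and restores the
global RNG state afterwards, so whole-bundle runs are byte-reproducible
(`run_case_study()` on the same config and seed rewrites identical JSON).
The validation suite uses 35–120 s respiration traces (up to 100 of them
for the classifier study), 60 s accelerometry at 256 Hz, an 8-minute
feature pair for warp recovery, and 200 × 1000 permutation replicates for
null calibration; the demo concert is 4–5 minutes end to end. These sizes
were chosen so the full suite exercises every property at realistic scale
in a couple of minutes on one CPU.

## What passing tests do and do not show

The generator emulates the *structure* of the study signals — quiet-cycle
morphology, the four disruption shapes, adaptive gain, gravity-plus-jolt
accelerometry, tempo-warped performance pairs with consistent annotations —
under white sensor noise. It does not emulate breathing-rate drift,
movement artefacts in the belt, coloured sensor noise, or real orchestral
audio; CQT behaviour is validated on pure tones and synthetic feature
matrices stand in for spectrograms in the warp tests. Green tests therefore
demonstrate correctness of the algorithms under the stated signal model,
not field performance on any particular sensor. Threshold defaults are
starting points for real recordings, and the classifier's output should be
read together with the logged configuration that produced it — which is why
`run_case_study()` always writes the thresholds into its summary.
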