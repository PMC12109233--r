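# concertphys

Audience psychophysiology from wearable sensors at live concerts: breath-by-
breath respiration analysis, quantity of motion, cross-performance alignment,
and event–phase coincidence statistics, with a synthetic-data generator so
every stage is testable without concert recordings.

## The problem

Seated listeners default to *quiet breathing*: an active inspiration of about
1 s, elastic expiration to a stable baseline, a short pause, and periods of
roughly 3–4 s. Deviations — spontaneous augmented breaths of ≥ 3× the quiet
depth, rapid "snuck" inspirations, long held breaths — can mark moments where
a listener's body engages with the music. Relating those moments to a score
requires four pieces of machinery, which this package provides for
researchers working with chest-belt respiration (≈26.5 Hz), core-body
accelerometry (≈256 Hz), and time-stamped musical annotations:

* **Breath segmentation and classification.** `segment_breaths()` finds
  inspiration onsets (troughs before a prominent rise) and expiration onsets
  (the following peaks); `compute_cycle_features()` adds relative depth and
  change-from-previous-cycle features; `classify_breaths()` labels each cycle
  quiet or disrupted, with flags for augmented (`rel_depth ≥ 3`), rapid, and
  held breaths. `quiet_fraction()` summarises any interval, time- or
  count-weighted.
* **Quantity of motion.** `resample_accel()` (anti-aliased, to 25 Hz) and
  `quantity_of_motion()` — the jerk magnitude `‖Δa‖·f_s`, invariant to
  gravity/posture offsets — plus robust-z `detect_jolts()`.
* **Alignment.** `cqt_spectrogram()` (one bin per semitone, C1–C7, hop
  23 ms), `dtw_align()` (compiled dynamic time warping, cosine distance on
  log-compressed frames), `warp_times()` to carry annotations and signal
  time stamps across performances, and `detect_held_passages()` for
  intervals without new onsets.
* **Coincidence.** `phase_event_coincidence()` counts events with a breath
  onset within ±0.5 s; `coincidence_null()` computes a circular-shift
  permutation p-value, `p = (1 + #{null ≥ obs})/(1 + N)`; `cohort_summary()`
  compares a participant's quiet fraction to the cohort median.

The synthetic module (`generate_quiet_breathing()`, `inject_disruptions()`,
`emulate_sensor_adaptation()`, `generate_motion()`,
`generate_performance_pair()`) produces all inputs with ground-truth ledgers.

## Worked example

A complete synthetic "concert" (5 minutes, two tempo-warped performances,
three injected breathing disruptions, two motion jolts) and the full
analysis:

```r
library(concertphys)
cfg <- make_demo_dataset(seed = 42, out_dir = "concert")
res <- run_case_study(cfg)

summary(res$cycles)
#> 83 breath cycles; median period 3.55 s, median depth 0.993
#> quiet 78 / disrupted 5; quiet time-fraction 0.920

res$jolts
#>     time magnitude
#> 1  90.04  28.33779
#> 2 186.04  30.08072

res$coincidence$entry
#> <coincidence_report> 1/15 events hit (tolerance 0.5 s, symmetric)
#> permutation null: mean 4.25 hits, p = 0.995 (1000 shifts)

res$warp
#> <warp_map> 13980 pairs, B [0.00, 316.34] s -> A [0.00, 299.99] s (mean slope 0.948)
```

Reading the output: 83 cycles were segmented, and 92.0% of the piece's
duration was quiet breathing — the three injected disruptions plus the two
cycles immediately after the large ones (the change-from-previous features
react one cycle late, by definition). The two jolts injected into the
accelerometry at 90 s and 186 s are recovered to within one QoM sample. The
breathing onsets of this simulated listener are unrelated to the
instrument-entry annotations, and the permutation test says exactly that
(p ≈ 1); planting onsets on the events drives p to the resolution floor
(~0.001 at 1000 permutations). The warp map relates the second performance's
316 s to the first one's 300 s. All file outputs (per-breath table, QoM
series, jolt events, warp CSV, warped annotations, per-category coincidence
JSON, summary JSON with the exact thresholds used) land in `concert/out/`,
and rerunning with the same seed rewrites them byte-identically.

See `vignettes/methods.Rmd` for the signal model, threshold rationale, and
numerical choices.

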