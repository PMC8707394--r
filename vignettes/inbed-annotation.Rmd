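---
title: "Annotating in-bed periods from dual-site accelerometry: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating in-bed periods from dual-site accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actibed)
```

## The problem

Supervised models of sleep and 24-h movement behavior need raw accelerometer
data with trustworthy labels, but large free-living datasets usually lack
sleep records. The workflow this package supports sidesteps that: the raw
hip and thigh signals are condensed into a handful of visually
interpretable channels, a human rater scrolls through them in Audacity (an
audio editor that handles many parallel tracks and long time series
fluently) and marks each night's to-bed and out-of-bed timestamps, and those
timestamps are then evaluated as measurements — against an EEG-based sleep
device, against a diary, between raters, and between repeated rounds by the
same rater.

The package implements every computational step of that workflow. The only
part it deliberately does not do is the human looking at the screen.

## Signal model and the seven channels

Recordings are tri-axial acceleration in g, with the device x axis along the
longitudinal axis of the body segment (positive toward the head when
upright). Sensors of this class are typically configured at ±8 g; values
outside that range are clamped (or rejected) on ingestion.

Processing happens in 2-s windows of 60 samples with 50% overlap, one output
frame per second. The windowed quantities are:

* **Inclination** θ = arccos(x̄/‖m̄‖), where m̄ is the window-mean
  acceleration vector. Under quasi-static conditions m̄ is gravity, so θ is
  the segment's tilt from upright: 0° aligned with gravity-up, 90°
  horizontal, 180° inverted. A zero-magnitude mean vector leaves θ
  undefined; the frame is marked missing.
* **SDacc**, the population SD (divide by n) of the longitudinal-axis
  samples — a movement-intensity proxy. Population rather than sample SD
  because the window is treated as the complete signal of interest, and at
  n = 60 the distinction is negligible anyway.

The 60-sample window implies a 30 Hz grid. Devices commonly record at
50 Hz, so recordings are linearly interpolated onto 30 Hz before windowing;
the target rate is configurable. Linear interpolation is adequate because
every downstream quantity is a 2-s window statistic.

From these, per frame:

* **Activity** — a thigh-based decision rule in the style of the
  free-living posture classifiers built on thigh inclination and movement:
  thigh inclination ≤ θ_sit means upright (standing, moving or walking, all
  encoded +1); inclination > θ_sit with SDacc ≤ s_move means sitting (0);
  inclination > θ_sit with SDacc > s_move means other activity (−1).
  Defaults θ_sit = 45° and s_move = 0.1 g are conventional values for this
  family of classifiers; the source publications of those classifiers, not
  this package, are authoritative for them, and both are configurable.
* **Lying** — true iff hip inclination **strictly exceeds 65°** and the
  thigh is concurrently classified as sitting. The strict inequality at 65°
  is kept exactly as specified; a sweep over integer angles with the thigh
  held at sitting flips from not-lying to lying between 65° and 66°.
* **Time of day** — six left-closed, right-open 4-h bins in local clock
  time mapped to six evenly spaced levels from −1 (00:00–04:00) to +1
  (20:00–24:00). Only the anchoring of the first bin at −1 is externally
  fixed; even spacing of 0.4 across the remaining bins is this package's
  choice, made so that the channel is monotone in clock time and visually
  unambiguous.

All channels are encoded into [−1, 1] for display as audio tracks:
inclination as θ/180 (so the channel occupies [0, 1]; no sign convention
distinguishes forward from backward lean, so the negative half of the
display range is deliberately unused), SDacc as −1 + 2·min(sd, 0.5)/0.5
(0 g maps to −1, "no movement"; saturation at 0.5 g keeps resting-level
variation visible instead of letting rare large spikes set the scale),
lying as ±1, activity and time verbatim.

Frames are marked missing when either site has a flagged recording gap
overlapping the window or an undefined inclination. Missing frames are
written to the WAV as 0.0 — keeping tracks continuous for visual
inspection — and tracked in the JSON sidecar so they round-trip as `NA`.

## Audacity bridge

One 7-channel IEEE-float32 WAV at a nominal 1 Hz header rate holds all
channels; a single drag-and-drop imports them as seven parallel tracks.
Label tracks export from Audacity as tab-separated `start end text` lines in
decimal seconds; the package writes the same dialect with 6-decimal seconds
so a read–write cycle is byte-identical. Only the region endpoints are
semantic; the label text is free-form. Absolute time comes from the sidecar:
event = recording start + label offset.

Nights are identified by a **noon rule**: an event belongs to the calendar
date of its evening — to-bed at or after 12:00 keeps its date, to-bed after
midnight belongs to the previous date. Any rule would do as long as every
event source shares it; noon is the natural cut for overnight behavior, and
the same rule is applied to labels, EEG-derived events and diaries.

## Ground truth from EEG epochs and diaries

EEG epoch records arrive as 30-s sleep-stage epochs including a
sensor-problem code. The in-bed event for a night is the span from the start
of the first non-sensor-problem epoch to the **end** (start + 30 s) of the
last one — an epoch denotes an interval, so using its end avoids a
systematic 30-s truncation. A night whose recording begins or ends with a
sensor-problem epoch is discarded outright: the device state at the
boundary is unknown, so the endpoint cannot be trusted. Sensor problems
strictly in the interior leave the endpoints untouched. Both rules are
tested exhaustively over all boundary patterns of up to four epochs.

No public schema exists for these exports, so the package defines plain CSV
dialects (`subject,night,epoch_start,stage` and
`subject,date,to_bed,out_of_bed`) and documents them as its interchange
format. Diary clock times roll over midnight by clock comparison, and a
reported to-bed before noon is taken to fall on the morning after the diary
date.

## Agreement statistics

Endpoints are paired night-by-night (inner join on subject × night,
complete cases only, no imputation) and expressed in minutes relative to the
night's reference midnight, so evening times are negative and morning times
positive — a scale on which a minute is a minute regardless of the clock
date.

**ICC.** The intraclass correlation is the two-way random-effects,
absolute-agreement form: ICC(2,1) for single measures, ICC(2,k) for the
average of k raters. The form is a package decision — absolute agreement is
the variant that penalizes systematic offsets between methods, which is
exactly what matters when two devices are supposed to report the same clock
time. Estimates come from the mean squares of the two-way ANOVA
decomposition; 95% CIs use the F-distribution interval with the
Satterthwaite-style effective degrees of freedom, and the average-measures
interval is the Spearman–Brown transform of the single-measures one.
Interpretation (poor < 0.5 ≤ moderate < 0.75 ≤ good < 0.9 ≤ excellent) is
read from the CI lower bound — the conservative convention. Band closure at
the cut points (left-closed) is a package decision. Two degenerate cases are
signalled distinctly: zero total variance (ICC undefined — a distinct
condition class) and zero within-row variance (the interval collapses to
the estimate). The average-measures transform can push a pathological lower
bound outside [−1, 1]; the raw value is reported and only the
interpretation input is clamped.

**Bland–Altman.** Differences are oriented **reference − test**, so a
positive bias means the test method timestamps events earlier than the
reference. Bias is the mean difference; limits of agreement are
bias ± 1.96·SD (a configurable multiplier, with 2.0 available for the older
"two standard deviations" convention); the bias CI is the t interval
bias ± t·SD/√n; the LOA CIs use SE_LOA = √(3·SD²/n) with the same t
quantile. The package always reports loa_lower ≤ loa_upper.

**Densities.** Difference distributions are summarized by a Gaussian kernel
density with Silverman's rule-of-thumb bandwidth; zero-variance input
returns an explicit degenerate-spike representation rather than a silent
zero-bandwidth failure.

## What the simulator emulates — and what it does not

The generator produces complete synthetic studies at the scale and noise
level of a typical free-living annotation study:

* **Cohort**: 10 subjects × 7 nights by default. Subject mean bedtimes are
  drawn around 22:30 with a between-subject SD of 90 min — wide because a
  cohort mixing children (early bedtimes) and adults (late bedtimes) spreads
  night-level times far more than any single adult's schedule — plus a
  night-to-night SD of 30 min.
* **Raters**: each rater/round annotates every endpoint as truth +
  Normal(bias, 14 min); 14 min is the noise scale at which manual
  annotation against an EEG reference typically operates. Default
  per-rater biases are a few minutes at most.
* **EEG device**: endpoints jittered by Normal(0, 5 min), snapped to the
  30-s epoch grid, tiled with plausible stage labels; with probability 0.05
  a boundary epoch is flagged as a sensor problem (such nights are
  discarded downstream), and occasional interior sensor-problem runs
  exercise the endpoint-invariance rule.
* **Accelerometry**: gravity projection per posture (e.g. in-bed: hip
  inclination uniform in 70–110°, thigh near-horizontal and still; walking:
  near-upright with 0.3 g longitudinal noise) plus white noise.

Under the default seed this produces the regime the workflow is known for:
ICC lower confidence bounds above 0.9 and limits-of-agreement half-widths
of roughly 20–40 min for single-rater-versus-EEG comparisons (these are
recomputed, not asserted from literature, in the test suite). Because the
checks are stochastic regime checks, individual alternative seeds can land
a lower bound slightly below 0.9; that is sampling variability, not a
pipeline change.

The simulator is deliberately simple where realism would not change what is
being tested: segment orientations are constant (no postural drift or sleep
micro-movements), noise is white (no device-specific spectra), there is no
non-wear, napping is not modelled, and rater errors are independent across
endpoints and nights. Passing tests therefore demonstrate the correctness
of the computational pipeline under controlled conditions — not that human
raters will achieve any particular accuracy on real recordings.

## Numerical choices and problem sizes

* Resampling is linear interpolation; window statistics are computed with
  cumulative sums, exact to double precision and O(N).
* Second offsets inherit the ~10⁻⁷ s precision of POSIX epoch doubles;
  label files carry 6-decimal seconds.
* The end-to-end signal test renders one subject-night (~10⁷ samples per
  site at 30 Hz) noiselessly and requires the automatically proposed in-bed
  labels to recover the true interval within 2 min; classifier-level checks
  use hour-long segments and require ≥ 95% correct interior frames (100%
  in the noiseless limit). Agreement checks use 50 random matrices
  (5–50 × 2–5) against an independent reference ICC implementation, 200
  replicates of n = 100 nights for bias-recovery coverage, and one
  10 × 7-night study for the regime check — sizes chosen to make the
  statistical assertions sharp while keeping the default suite quick to
  run.

## Known limitations

* The activity classifier is an approximation of the published
  thigh-accelerometer decision rules; its thresholds are conventions, not
  calibrated constants.
* Inclination is unsigned; forward and backward lean are indistinguishable,
  which is why half the documented display range of the inclination
  channels is unused.
* The EEG reference measures *device-on* time, and diaries measure
  *reported* time; neither is the same construct as in-bed time from
  accelerometry. The agreement statistics quantify, but cannot remove, that
  construct gap.
* Clock synchronization between devices is assumed; no drift correction is
  attempted.
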