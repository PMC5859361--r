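---
title: "Methods: perception-based cooling sessions, shiver detection, and the participant simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perception-based cooling sessions, shiver detection, and the participant simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coolprotocol)
```

`coolprotocol` implements the computational side of individualized,
perception-based cold-exposure studies: sessions in which a participant lies
on water-circulating blankets, rates their thermal perception on a 0-100
slider ("Very Cold" to "Very Hot") with a binary shiver indicator, and the
water temperature is lowered phase by phase according to those ratings until
sustained shivering ends the session. This vignette describes the models and
procedures the package implements, the parameters that matter, the numerical
choices made where the underlying protocol description leaves room, and what
the simulator-based tests do and do not establish.

## EMG shiver-event detection

Surface EMG (trapezius/sternocleidomastoid, 1,000 Hz) is processed as:

1. **Filtering.** A zero-phase 4th-order Butterworth band-pass, 20-400 Hz,
   followed by a second-order notch at 60 Hz (quality factor 30). In the
   original acquisition chain these filters were analog, applied before
   digitization; realizing them digitally with forward-backward
   (`filtfilt`) application keeps the passband shape while adding no phase
   lag, so detected onsets are not biased late. A narrow notch leaves a
   short edge transient at the very start and end of a trace; baselines and
   events of interest sit well inside the recording in practice.
2. **Teager-Kaiser energy operator.** `psi[n] = x[n]^2 - x[n-1] x[n+1]`,
   which for a sinusoid of amplitude A and digital frequency w equals
   `A^2 sin(w)^2`: energy rises with both amplitude and frequency, which
   sharpens burst onsets against low-level baseline activity. Boundary
   samples copy the nearest interior value so lengths are preserved.
3. **Envelope.** Rectification then a zero-phase 4th-order low-pass at
   50 Hz.
4. **Baseline and threshold.** A quiet segment of about 5 s provides the
   baseline mean and standard deviation (mu, sigma); the detection
   threshold is `mu + J sigma` with `J = 15`, a preset validated for
   low-magnitude muscle-activity baselines. In the original workflow the
   resting segment was chosen by an operator; for reproducibility the
   package scans the trace for the contiguous 5 s window of minimum
   envelope variance (earliest window on ties) and lets explicit bounds
   override it. If no quiet window exists — e.g. a short trace with a
   burst in the middle — the automatic choice degrades (sigma is inflated
   by the burst and the threshold can rise above the bursts themselves),
   which is why traces should include a resting period, as recorded
   sessions naturally do. A zero-variance baseline degenerates the
   threshold to the mean and is flagged with a warning.
5. **Onset criterion.** A sample is an onset candidate when it is strictly
   above threshold and at least 10% of the samples in its 250 ms window are
   strictly above threshold. The published rule does not say how the window
   is anchored; the package anchors it forward (`[t, t + 250 ms)`) by
   default, which ties the event to its first sample, and exposes
   `center`/`backward` anchoring as options. Samples beyond the trace ends
   count as sub-threshold, a conservative choice for bursts running into
   the edge of a recording.
6. **Events.** Each maximal supra-threshold run containing at least one
   qualifying sample becomes one event: onset at its first qualifying
   sample, offset just past its last supra-threshold sample. Events are
   half-open intervals, so inter-event gaps equal the sub-threshold spans
   between runs exactly. Events separated by strictly less than 50 ms are
   merged (a gap of exactly 50 ms keeps them separate; comparisons carry a
   1 ns guard so the boundary is decided by arithmetic, not floating-point
   representation). Merging is idempotent.

The detector is vectorized (cumulative sums for the window counts); the test
suite holds it to exact agreement with an exhaustive per-sample window-scan
implementation on randomized short traces, and to recovery of >= 90% of
injected bursts (amplitude ratio >= 5, duration >= 300 ms) with onset error
<= 50 ms across seeds.

Channel handling: recordings are detected per channel; when several muscles
are recorded, run the detector per trace and combine event tables as the
analysis requires (the union view is what the similarity analysis uses).

## Self-report analytics and similarity fractions

Self-reported shiver intervals are the maximal runs of shiver flag = 1 in
the tGUI log; an interval still open at the end of the log closes at the
last timestamp. The agreement between EMG and self-report is summarized by
two similarity fractions:

- EMG fraction = matched events / number of EMG events,
- tGUI fraction = matched events / number of tGUI events,

with a fraction defined as 0 when its denominator is 0. The published
definition counts "intersecting" events without stating when an EMG event
and a self-reported interval correspond, and the published ranges cannot pin
the rule down. The package therefore makes the correspondence rule explicit
and configurable: each self-reported interval is expanded symmetrically by a
tolerance (default 2 s, motivated by self-report latency — a participant
reacts after the shiver starts and releases the button after it ends), and
events are matched greedily in chronological order, one-to-one, when the
intervals overlap. Because the rule changes the fractions, any reported
fractions should state the tolerance used.

## Physiological markers and skin-temperature analysis

Three markers characterize a session, each extracted with the comparator
the underlying definitions use:

- **Vasoconstriction index** — first time the forearm-minus-finger gradient
  reaches 4.0 degC (fires at `>=`, reading "equal to 4 degC" literally).
- **Shiver onset** — start of the first self-reported interval.
- **Sustained shivering** — start of the first self-reported interval
  strictly longer than 60 s, the protocol's termination criterion.

At each marker the water temperature and slider value are taken from the
common grid by nearest-prior sample rather than interpolation: the set
point is a step-like command and the slider a held state, so interpolating
across a step would fabricate intermediate values. The exclusion rule for
thermoneutral vasoconstriction uses the strict comparator its definition
quotes (gradient > 4 degC at the end of the thermoneutral phase). Relative
skin temperatures subtract each channel's value at thermoneutral end; the
gradient column stays absolute. Spearman correlations between the slider
and each channel use average ranks for ties (`stats::cor`), and are flagged
undefined below 3 complete pairs or for constant series.

Streams are aligned by a pure time shift (the start of the first cooling
phase becomes time zero; earlier samples keep negative times) and combined
on a common grid by linear interpolation within each stream's span, with no
extrapolation — out-of-span cells are missing, and the shiver flag is
carried forward as a state rather than interpolated.

## The protocol controller

The controller is a deterministic state machine over three phases:

- **pre-neutral**: the session starts at 32 degC with the slider expected
  at "Neutral". While the participant rates away from neutral, the water
  moves 1 degC toward them every 3 min (warmer when they feel cold, cooler
  when warm). The moment the slider reads neutral, the 15 min
  thermoneutral phase begins.
- **thermoneutral**: 15 min at the established temperature.
- **cooling**: successive 10 min phases. At each phase end the slider
  position sets the decrement for the next phase via a rule table.

The published material quotes two decrement rules (1 degC between "Very
Cold" and "Cold"; 3 degC at "Cool") and the principle that a slider aligned
with a landmark takes the smaller of the flanking decrements; the complete
table and the numeric landmark positions appear only in a figure whose text
is not legible in the source. The package's defaults are therefore a
reconstruction, clearly flagged as such and fully configurable: seven
equally spaced landmarks (neutral at 50), intervals of 5/3/1 degC moving
coldward from neutral, landmark values obeying the smaller-decrement rule,
and the maximum decrement (5 degC) for ratings warmer than neutral at a
cooling-phase end (the controller never re-warms during cooling). Alignment
with a landmark means within 1 slider unit, the scale's integer resolution.
A configurable floor (default 4 degC) reflects what a circulating-water
chiller can practically deliver; decrements clamp there and the session
continues.

Termination is strict: a self-reported interval must exceed 60 s
(`> 1 min`), and the session ends at the first observable instant — a log
row or controller step — past `onset + 60 s`. Probing the boundary with
single intervals on a 1 s grid yields exactly the 1 min threshold.
The familiarization schedule is fixed: seven 8-min stages at
32/22/19/16/13/10/7 degC.

## The participant simulator

The simulator exists to close the loop for testing, with ground truth
attached; it is deliberately the simplest model that reproduces the
qualitative physiology the analysis code must handle, not a validated
thermoregulation model.

- **Skin**: each site (clavicle, forearm, finger) follows a first-order lag
  `dT/dt = (T_target - T)/tau` with `T_target = baseline - gain (32 -
  T_water)`. Integration uses one exact exponential update per 30 s step
  with the water temperature held constant within the step, so the 63%
  closure after one time constant is exact. Defaults (tau 12/8/3 min, gains
  0.08/0.25/0.65) give the observed ordering of responses — finger drops
  most, forearm less, clavicle least — and a growing arm-to-finger gradient
  under cooling. Below a water temperature of 26 degC the finger gain rises
  by a factor 1.35, a crude stand-in for cold-induced vasoconstriction;
  `clavicle_mode = "warming"` adds a slow positive drift once the gradient
  reaches 4 degC, emulating the supraclavicular warming observed in a
  subset of individuals (a surrogate sign of brown-adipose-tissue
  thermogenesis).
- **Perception**: slider = `round(clip(50 + slope (mean skin - midpoint) +
  noise))`, with the midpoint defaulting to the baseline mean skin
  temperature so a resting participant rates neutral. The default slope of
  6 slider units per degC makes default closed-loop sessions terminate
  after 4-6 cooling phases across seeds, matching the session lengths such
  protocols produce in practice; steeper slopes shorten sessions, shallower
  ones lengthen them.
- **Shivering**: below a susceptibility level (default 30) the per-sample
  shiver probability rises linearly to 1 at slider 0, and drawn events last
  5-45 s; at or below the sustained level (default 10) the flag locks on,
  which the controller then terminates. Ground-truth intervals are recorded
  exactly as drawn.
- **EMG**: band-limited Gaussian noise whose amplitude is multiplied by the
  burst ratio inside ground-truth intervals.

One seed drives a session; the EMG sub-stream derives its seed
deterministically from it, so full sessions are bit-reproducible. Closed-loop
sessions that fail to terminate by the 4 h cap (e.g. a participant whose
perception barely responds, reaching the temperature floor without
shivering) are flagged in metadata rather than raised as errors.

What passing simulator-based tests shows: the detector, controller, and
marker extraction are mutually consistent and recover known ground truth
through the full write/read/synchronize/detect path at the cadences and
magnitudes of real sessions. What it does not show: performance on real
EMG (motion artifacts, non-shiver muscle activity, electrode noise are not
modelled — the moderate/poor agreement seen between EMG and self-report in
real recordings comes precisely from such confounds), nor validity of the
thermal parameters for any actual population.

## Problem sizes and runtime choices

The test suite runs detector-oracle equivalence on traces up to 10 s,
burst-recovery over 20+ seeds of ~10-20 s traces, and three full
closed-loop sessions plus several shorter ones; the whole suite completes
in well under a minute on one CPU. Sessions simulate at 30 s cadence (the
logging cadence of the instruments), and synthetic EMG is generated at
1,000 Hz only for the spans a test needs.

## Known limitations

- The decrement table and landmark positions are reconstructions
  (configurable); absolute water temperatures from the controller should
  not be read as the published protocol's exact values beyond the quoted
  1 degC / 3 degC rules and timing constants.
- The similarity fractions depend on the matching tolerance; there is no
  published rule to validate against.
- Per-channel EMG detection with event-table union is one of two plausible
  readings of "combined" multi-muscle activity (the other being summing
  signals before detection).
- The LabChart-style reader targets tab-delimited numeric exports with a
  textual header block; exotic export variants may need the canonical CSV
  route.
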