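# coolprotocol

Tooling for **individualized, perception-based cooling protocols** — the
cold-exposure paradigm used to study human thermoregulation and brown
adipose tissue (BAT) activity. In such a session the participant lies on
water-circulating blankets, continuously rates thermal perception on a
0–100 slider ("Very Cold" → "Very Hot") with a binary shiver indicator,
and the water temperature is lowered in 10-min phases according to those
ratings — starting from a 15-min thermoneutral phase at a temperature the
participant rates "Neutral" — until self-reported shivering is sustained
for more than one minute.

The package is for researchers running or analyzing these sessions. It
provides:

- **EMG shiver-event detection.** Zero-phase band-pass (20–400 Hz) and
  notch (60 Hz) filtering, the Teager–Kaiser energy operator
  ψ[n] = x[n]² − x[n−1]·x[n+1], rectification and 50 Hz low-pass
  enveloping, a detection threshold *y* = μ + *J*·σ over a ~5 s resting
  baseline (*J* = 15), onset at the first sample that exceeds the
  threshold with ≥ 10% of its 250 ms window supra-threshold, and merging
  of events separated by < 50 ms.
- **Self-report analytics.** Shiver intervals from the slider log, and
  EMG↔self-report *similarity fractions* (matched events divided by each
  source's event count) under an explicit, tolerance-padded one-to-one
  matching rule.
- **Physiological markers.** Vasoconstriction index (forearm-minus-finger
  skin gradient reaching 4 °C), shiver onset, and sustained shivering,
  with water temperature and perception extracted at each; the strict
  > 4 °C thermoneutral exclusion rule; relative skin temperatures and
  Spearman correlations between perception and skin channels.
- **A protocol controller.** The perception-guided cooling protocol as a
  deterministic state machine (slider→decrement rule table, 3-min
  thermoneutral adjustments, strict >1 min termination), plus the fixed
  seven-stage familiarization schedule (32→7 °C).
- **Session IO.** Canonical CSV log formats for water/tGUI/skin/EMG
  streams, a LabChart-style reader, clock synchronization (time zero =
  start of the first cooling phase), and common-grid resampling.
- **A participant simulator.** First-order-lag skin thermodynamics, a
  noisy perception model, probabilistic shiver self-reports and synthetic
  EMG, run in closed loop with the controller and carrying exact ground
  truth — so the whole stack is testable without human data.

## Worked example

Simulate a complete closed-loop session with synthetic EMG, then analyze
it exactly as a recorded session would be:

```r
library(coolprotocol)

sim <- run_closed_loop(participant_model(seed = 42), emg = TRUE)
as.data.frame(sim$truth$phases)
#>            kind index start  end set_temp_c
#> 1      pretrial    NA  -930 -900         32
#> 2 thermoneutral    NA  -900    0         32
#> 3       cooling     1     0  600         27
#> 4       cooling     2   600 1200         22
#> 5       cooling     3  1200 1800         19
#> 6       cooling     4  1800 2400         16
#> 7       cooling     5  2400 2580         15
```

Times are seconds with zero at the start of the first cooling phase. This
participant needed one pre-neutral adjustment check, held thermoneutral at
32 °C, was cooled 27 → 22 → 19 → 16 → 15 °C as their ratings moved down
the scale (decrements of 5/3/1 °C per the rule table), and terminated in
the fifth cooling phase: the *shivering water temperature* is 15 °C.

Detect shiver events in the synthetic EMG and compare them with the
self-report:

```r
det <- detect_shiver(sim$bundle$emg)
det
#> <shiver_detection> 21 event(s); threshold 0.0009959 (mu 0.0001246, sigma 5.809e-05)
#>   events span 809.998 .. 2580.000 s

similarity_fractions(det$events, tgui_intervals(sim$bundle$tgui), tolerance = 2)
#> <similarity_result> 21 EMG, 21 tGUI, 21 matched (tolerance 2 s)
#>   EMG fraction 1.000, tGUI fraction 1.000
```

All 21 injected bursts are recovered and matched one-to-one — fractions of
1.0 are the clean-signal ceiling; real EMG carries non-shiver muscle
activity that lowers them. Extract the three physiological markers:

```r
as.data.frame(detect_markers(sim$bundle))
#>                   marker present time water_temp_c perception
#> 1 vasoconstriction_index    TRUE  660           22         39
#> 2           shiver_onset    TRUE  810           22         26
#> 3       sustained_shiver    TRUE 2490           15          8
```

The gradient reached 4 °C at 660 s (water at 22 °C), the first
self-reported shiver came at 810 s, and the interval that terminated the
session began at 2490 s with the participant rating 8 ("Very Cold" side of
"Cold") — the within-session warm-to-cold ordering these protocols are
designed to resolve.

A command-line front end wraps the same functions
(`exec/coolprotocol`, installed with the package):

```sh
coolprotocol simulate --seed 42 --out session42 --emg
coolprotocol detect-shiver --session session42 --out det42
coolprotocol similarity --emg-events det42/emg_events.csv \
    --tgui-events session42/truth_events.csv
coolprotocol summarize --session session42 --out summary42
coolprotocol schedule          # familiarization guide, 32 -> 7 degC
```

See `vignettes/cooling-protocol-methods.Rmd` for the models, parameter
defaults, and the design decisions behind the reconstructed decrement
table and the matching tolerance.

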