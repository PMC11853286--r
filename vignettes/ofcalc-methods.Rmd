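---
title: "Shuffle-based classification of shock-responding cells: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shuffle-based classification of shock-responding cells: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ofcalc)
```

## The problem

During observational fear, a mouse watches a conspecific receive brief foot
shocks and itself expresses fear (freezing). One-photon calcium imaging of
the observer's anterior cingulate cortex (ACC) yields, after ROI extraction,
a 20 Hz fluorescence trace per accepted cell. The scientific questions this
package addresses are: which cells increase (or decrease) their transient
rate at the moments the demonstrator is shocked; whether optogenetic
inhibition of the mediodorsal-thalamus-to-ACC projection during the shock
abolishes that response; and whether the observer's freezing differs between
the light-OFF and light-ON halves of the session.

`ofcalc` implements that analysis as a deterministic, seeded pipeline
operating on exported traces, a GPIO synchronization record, an experiment
schedule, and a manually scored behavioral event log — plus a synthetic
session generator with planted ground truth so every stage is testable
without any recording.

## The protocol timeline

A session is a 300 s habituation followed by 20 shocks of 2 s, separated by
inter-trial intervals drawn uniformly from 30–60 s (randomized so the
demonstrator cannot anticipate the shock). The inhibitory LED is off for
shocks 1–10 (the OFF trials) and on for shocks 11–20, illuminating from 1 s
before each shock to 1 s after (a 4 s window). `generate_schedule()`
reproduces this timeline; with a mean ITI of 45 s the shock phase lasts
about 940 s, and the generated phase always falls in the feasible
640–1240 s range. For a non-default shock count the first `ceiling(n/2)`
shocks are the OFF trials, matching the 10/10 split at n = 20.

All times are seconds from experiment start. The imaging clock is aligned by
subtracting the GPIO trigger time (`align_to_experiment_start()`); samples
recorded before the trigger are discarded rather than kept at negative
times, since no schedule event can refer to them. Every analysis window is
half-open `[start, end)`, so an event on a shared boundary is counted
exactly once.

## Transient detection

A calcium "spike" is a strict local maximum of the trace above
`baseline_mean + 2 * baseline_sd` (the multiplier is configurable). Two
baseline conventions are exposed because the notion of "baseline" is
genuinely ambiguous for a whole-session recording:

* `"full"` (default): mean and sample SD of the entire trace — the simplest
  convention, used throughout the tests;
* `"habituation"`: mean and SD of the first 300 s only, which excludes
  shock-evoked transients from the baseline estimate.

One contiguous supra-threshold excursion yields one event, timestamped at
its maximum sample, so a single transient cannot be counted repeatedly;
surviving peaks closer than 0.25 s (about the transient rise time) are
merged to the larger one. Exceedance is strict: a peak exactly at threshold
is not an event. The SD is the sample (n−1) convention — immaterial at
24,000 samples but fixed for reproducibility. NaN samples (dropped frames)
are excluded from the baseline and can never be peaks.

Detection is shift- and scale-equivariant (the threshold moves with the
trace), and raising the multiplier can only remove events; both properties
are asserted in the test suite.

## The shuffle null and cell classes

For each cell, the observed statistic is the mean event rate over the ten
2 s shock windows of a condition. Its null distribution is built by
circularly shifting the entire event train by increments drawn uniformly
from 20–1200 s — wrapping modulo the session length, which conserves the
event count and the circular inter-event structure — and recomputing the
window rate, 1000 times. Percentiles of the null use linear interpolation
between order statistics (R's default type 7), cross-checked in the tests
against an independent sort-and-index oracle and a brute-force recount of
the shuffled rates.

* **SRC** (shock-responding cell): observed OFF-window rate strictly above
  the null's 95th percentile.
* **SSC** (shock-suppressed cell): observed OFF-window rate strictly below
  the null's 5th percentile.
* **Suppressed SRC**: an SRC whose ON-window rate, tested against a fresh
  shuffle null computed over the ON-trial shock windows, no longer exceeds
  that null's 95th percentile.
* **ON-only SRC**: a cell that is not an SRC but whose ON-window rate
  exceeds its ON null's 95th percentile.

Wrapping (rather than truncating) the shifts is the defensible default: a
non-wrapping shift would push events off the end of the session and bias
null rates downward. The ON-condition windows are the 2 s shock windows of
the ON trials, not the 4 s LED windows — rates are computed "during the
shock moment" in both conditions — though LED-window analysis is available
via `window_kind = "led"`. An empty train is never significant in either
direction: its observed rate 0 can neither strictly exceed nor fall below a
degenerate null at 0, consistent with the strict inequalities. Cells are
analyzed per session; no cross-session matching is attempted, and no
multiple-testing correction is applied across cells (per-cell calls are
reported raw, as is conventional for this shuffle criterion).

## Summary statistics

`summarize_counts()` recomputes every percentage from its own counts,
rounded to one decimal: 27 SRCs of 391 cells is 6.9%, and 26 suppressed of
27 SRCs is 96.3% (26/27 = 96.296...; the package always emits the computed
value). The suppression count is tested with a two-sided Pearson chi-square
against a 50/50 split *without* continuity correction — the convention
pinned by the worked example, where counts (26, 1) give X² = 23.148 with
df = 1 and p < 0.0001 (Yates' correction would give 21.3). Freezing metrics
are compared across sessions with a two-tailed paired t-test (df = n − 1);
identical pairs make the statistic undefined and are flagged rather than
reported as a number. p-values are formatted to four decimals, with values
below 0.0001 reported as "< 0.0001".

## Freezing-bout metrics

Freezing epochs come from a BORIS-style START/STOP event log. Abutting
epochs (zero gap) are merged first, then only bouts with duration *strictly*
greater than 2 s are accepted. A bout belongs to a condition period by its
start time ("began during the designated time period"); a bout straddling
the OFF-to-ON boundary counts once, toward the condition where it began,
with its full duration credited there (clipping is available via
`clip_to_period` but off by default, since the convention is membership by
onset, not occupancy). Per period the package reports the bout count, total
and percentage freezing time, mean bout duration, and the mean duration of
bouts beginning inside a 2 s shock window. The OFF period runs from the
first OFF shock onset to the first LED-window start, and the ON period from
there to session end; the comparison windows are not uniquely determined by
the protocol description, so this boundary choice is explicit, documented
and configurable.

## The synthetic-data generator

The generator emulates exactly the statistical structure the analysis
assumes, with known ground truth:

* **Events** are piecewise-homogeneous Poisson: each cell fires at its
  baseline rate everywhere except inside shock windows, where the rate
  switches to the class-appropriate OFF/ON value. Class defaults (chosen
  once as the study conditions for all recovery experiments): SRC-type
  cells 0.05 events/s baseline with 2 events/s in responsive windows — a
  40-fold effect, comfortably in the strong-effect regime; NULL cells
  homogeneous at 0.1 events/s, the rate used for type-I calibration; SSC
  cells 0.5 events/s baseline and 0 in shock windows, because a suppression
  call requires the null's 5th percentile to be positive, i.e. several
  baseline events per 20 s of shock window.
* **Traces** convolve the event train with a difference-of-exponentials
  kernel (rise 0.08 s, decay 0.5 s — GCaMP6f-like; peak lag ≈ 0.17 s), add
  a constant baseline and i.i.d. Gaussian noise with peak-to-noise ratio 6.
* **Synchronization**: raw traces start `gpio_offset` seconds before the
  experiment, and a GPIO record carries the rising trigger, so the
  alignment stage is exercised end to end.
* **Behavior** is a two-state (move/freeze) alternating-renewal process
  with exponential dwell times, plus a configurable probability that a
  shock interrupts movement with a bout starting inside the 2 s window. It
  exists to exercise the metrics code, not to model freezing dynamics.

All randomness flows from one master seed through deterministic sub-seeds;
identical seeds give bit-identical sessions and, through `run_pipeline()`,
byte-identical report files.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: correlated or non-Gaussian imaging noise,
photobleaching and slow baseline drift, motion artifacts, ROI
cross-contamination, bursting or refractory event statistics, and realistic
freezing dynamics. Recovery results on synthetic sessions demonstrate the
correctness of the statistical machinery under its own assumptions, not
detector performance on raw miniscope movies.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 200-seed Poisson moment
checks; 400 simulated null cells at 200 shuffles each for type-I
calibration (the reduced-shuffle option of the 1000-shuffle analysis
default); one 65-cell session (10 suppressed SRC, 5 non-suppressed SRC, 5
ON-only SRC, 5 SSC, 40 null) at 1000 shuffles for class recovery; and small
2–6 cell sessions for determinism and round-trip checks. These sizes give
stable Monte-Carlo behavior while keeping a full run to a couple of
minutes.

Tie-breaks and degenerate inputs are fixed as follows: within a
supra-threshold excursion the first maximal sample wins; merging keeps the
larger peak (ties keep the earlier); a schedule with a single shock has an
OFF half and an empty ON half, and suppression is then undefined; a
zero-variance paired test and an all-NaN trace are errors or flags, never
silent numbers.

## Known limitations

* **Dense cells and the 2-SD rule.** A cell firing at ~0.5 events/s
  summates transients (decay 0.5 s), which inflates the whole-trace mean
  and SD until the threshold approaches the single-event peak amplitude;
  detection then recovers only a fraction of the planted events. For SSC
  cells this lowers the null's 5th percentile toward ~1 event per 20 s,
  while events just before a shock onset leak into the window (the peak
  timestamp lags the event by ~0.17 s), so the strict below-p5 call becomes
  marginal: across master seeds, full-pipeline SSC sensitivity on 5 planted
  cells ranges roughly from 0.4 to 1.0. This is a faithful property of the
  2-SD whole-trace rule on dense cells, not of the classifier, which
  recovers SSCs reliably when applied to the event trains directly. The
  habituation baseline does not help here because an SSC cell is equally
  dense during habituation.
* **Strict-inequality conservatism.** With discrete event counts the null
  has ties, and the strict `> p95` rule calls slightly fewer than 5% of
  null cells significant (measured ≈ 3–5% across 400 cells); the
  classifier is conservative, never anticonservative.
* **ON-only calls are type-I limited.** An ON-only SRC is, by definition,
  a cell that fails the OFF test; any planted ON-only cell has a ~5%
  chance of (correctly by chance, wrongly by label) passing it, which
  bounds achievable labelling accuracy for that class near 95%.
* The trace reader supports a documented, simplified IDPS-like CSV dialect
  only; proprietary session files, video, motion correction and ROI
  extraction are out of scope.
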