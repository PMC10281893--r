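---
title: "Breathing irregularity metrics and desk-scale 4D CT acquisition simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breathing irregularity metrics and desk-scale 4D CT acquisition simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breath4dct)
```

## The problem

4D CT for radiotherapy planning reconstructs one 3-D image per breathing
phase (usually ten) from projection data correlated with a respiratory
surrogate signal.  Conventional scanners acquire spirally at a fixed low
pitch and sort the data retrospectively; when the patient breathes
irregularly — strong cycle-to-cycle amplitude differences, frequency
variability, breathing pauses — the data available for a given couch
position and phase become inconsistent or missing, producing
double-structure and interpolation artifacts.  Breathing-adapted sequence
scanning instead keeps the beam on at each couch position until real-time
signal analysis confirms that one representative breathing cycle has been
captured, then moves the couch.

`breath4dct` implements the signal-analysis side of comparing these two
strategies: quantifying breathing irregularity from surrogate traces,
selecting and matching irregular-breather cohorts by those statistics, and
simulating both acquisition modes on the signal level, with a synthetic
breathing generator providing ground truth for every stage.  No image
reconstruction is performed; the simulators reason purely about timing and
phase coverage, which is where the artifact mechanisms originate.

## The synthetic breathing model

Each cycle is a raised cosine-power pulse: within cycle $i$ of period
$\tau_i$, the amplitude is
$a \cdot \cos^{2k}\!\big(\pi (t - t_{\mathrm{peak},i}) / \tau_i\big)$ with
$k$ = `shape_exponent` (default 2).  The even power yields a single sharp
end-inhalation peak per cycle and a realistic dwell near the end-exhale
baseline.  Periods are drawn from a normal distribution truncated below at
half the mean period, amplitudes from a normal truncated at zero, so the
stated means and SDs hold approximately while degenerate cycles are
impossible.

Three construction details keep the ground truth exact and the trace
analyzable:

* **Continuity.** The descent half of cycle $i$ uses amplitude $a_i$; the
  ascent half blends to $a_{i+1}$.  The trace is continuous, peak $i$
  reaches exactly $a_i$, and the per-cycle excursion (peak minus following
  trough) equals $a_i$ by construction.
* **Margins.** A half-cycle ascent from baseline precedes the first peak
  and a half-cycle descent follows the last, so every true peak is an
  interior local maximum.  Total trace length is therefore the active
  breathing time plus inserted pauses plus these two margins.
* **Trimming.** The last cycle is shortened to land on the requested
  duration; when the remainder would be below half a mean period the
  partial cycle is dropped instead.  Extending a neighbouring cycle would
  fabricate a long inter-peak gap indistinguishable from a breathing
  pause.

Pauses are end-exhale baseline holds of exact, recorded duration inserted
at a cycle's mid-point; linear drift and white Gaussian noise are added
last.  One seed drives a single random stream, so signals are reproducible
bit for bit.

What the generator does *not* emulate: vendor-specific noise spectra,
cardiac ripple, nonlinear baseline shifts, posture changes, or
waveform-shape variability between patients.  Passing tests demonstrate
correct recovery of the model's ground truth under realistic noise, not
performance on arbitrary clinical exports.

## Preprocessing

The fixed order is window → drift correction → normalization:

1. **Windowing** restricts the curve to the span between the first and the
   last beam-on sample (inclusive), so that statistics describe breathing
   during scan time.  It is skipped when a trace carries no beam-on
   channel.
2. **Drift correction** subtracts the ordinary-least-squares line of
   amplitude versus time — the plainest reading of linear drift
   correction, estimated on scan-time data only because it runs after
   windowing.
3. **Normalization** affinely rescales to $[0, 1]$.  On the unit-range
   scale the per-cycle amplitude SD is a dimensionless fraction of the
   total breathing excursion, comparable across patients and cohorts; the
   scale and offset are kept in the provenance record so estimates can be
   mapped back to acquisition units.

The composition makes every downstream metric invariant under positive
affine transforms of the raw amplitudes, and insensitive (to well below
2%) to linear drift up to 0.05 a.u./s.

## Cycle analysis

End-inhalation peaks are strict local maxima with topographic prominence
of at least `min_prominence` (default 0.2 of the unit range), thinned so
consecutive peaks are at least `min_separation_s` apart (default 1 s,
admitting up to ~60 breaths/min; the higher peak wins a conflict).
"Inhalation points" are interpreted as end-inspiration *maxima*,
consistent with the inhale-positive amplitude convention; onsets would be
an alternative reading.

Detection and amplitude measurement run on a lightly smoothed copy of the
trace (centered moving average, default 0.2 s — an order of magnitude
below any breathing period).  Without it, the extreme-value statistics of
per-cycle maxima/minima over ~100 noisy samples bias every excursion
upward; with it, amplitude-SD recovery error drops to about 1% at noise
levels up to 5% of the mean amplitude.  The window is configurable and 0
disables smoothing.

Cycles are half-open peak-to-peak intervals.  The per-cycle
**peak-to-peak amplitude** is the amplitude at the cycle's own starting
peak minus the minimum inside the interval (its end-exhale trough).  A
max-minus-min definition over the same interval would instead return
$\max(a_i, a_{i+1})$ for any continuous trace — the interval ends just as
the signal reaches the *next* peak — letting a large neighbour contaminate
a small cycle's estimate; the excursion-from-own-peak definition measures
the individual cycle.

The **average breathing cycle** is the median of inter-peak durations.
An arithmetic mean would be inflated by the very pauses the 1.5× pause
rule must detect, making the rule partially self-defeating; the median is
pause-robust.  This is a deliberate robust reading of "average".

Phase bins are time-fraction bins: a sample at fraction $f$ of its cycle
gets bin $\lfloor f \cdot n_\mathrm{phases} \rfloor$ (default 10 bins).
Samples before the first or after the last peak are unassigned;
edge cycles are excluded from all statistics.

## Irregularity metrics, selection, matching

Two statistics summarize one curve after full preprocessing:

* `amp_p2p_sd` — sample SD ($n-1$) of the per-cycle excursions, on the
  unit-range scale;
* breathing pauses — inter-peak gaps of at least 1.5× the average cycle,
  attributed to the earlier peak with the full gap as duration (a literal
  reading of "maximum duration between two successive inhalation
  points"); `longest_pause_s` is 0 when no gap qualifies.

Cohort selection takes the top `n_amp` (default 15) curves by amplitude
SD, then the top `n_pause` (default 10) by longest pause among the
remainder — disjoint lists with the amplitude criterion taking precedence,
ties broken by curve id so the selection is deterministic.  Cross-cohort
matching is greedy nearest-neighbour without replacement in descending
order of the selection statistic; optimal (Hungarian) assignment and
multivariate similarity (frequency, cycle shape — a visual, human step in
practice) are out of scope.

## Acquisition simulators

Geometry is one-dimensional (couch axis only): artifact genesis is
temporal/phase consistency, not reconstruction physics.

**Spiral (retrospective gating).** Couch speed is
$v = p \cdot W / t_\mathrm{rot}$ for pitch $p$, collimation width $W$ and
rotation time $t_\mathrm{rot}$; each station of width $W$ is illuminated
for $t_\mathrm{rot} / p$ (≈5.6 s with the default 0.5 s / 0.09 protocol).
The beam is continuously on (duty cycle 1).  Per station and phase bin the
simulator selects, among acquired samples of that bin inside the
illumination window, the one whose phase fraction is closest to the bin
center (ties: nearest the window center) — mirroring how retrospective
binning targets a reconstruction phase; a cell with no candidate is
*missing*.  A station whose local cycle outlasts its illumination window
(slow breathing, pauses) inevitably misses bins.

**Sequence (breathing-adapted).** Reference statistics (median period and
excursion) are learned from the first `learning_cycles` cycles (default
3).  Per couch position (spacing = couch increment): beam on at the next
detected cycle start — a peak is confirmable one sample after its maximum,
honouring causality — and off one rotation time after the first completed
cycle whose duration and excursion lie within `period_tolerance` (0.35)
and `amp_tolerance` (0.25) of the reference, or after `max_dwell_s` (30 s,
position flagged incomplete).  The couch then advances during a dead time
(0.8 s).  The real scanner's on/off logic is proprietary; this
representative-cycle rule is an explicit, configurable stand-in, and the
clinical rotation-time auto-adaptation is modeled as a fixed configurable
value.  Phase coverage comes from the accepted cycle's samples (bin-center
selection as above).

**Artifact proxies.** `interpolation_count` is the number of missing
(position, phase) cells; `double_structure_score` is the mean absolute
amplitude difference between samples selected at adjacent positions for
the same phase, divided by the median cycle excursion — a surrogate for
motion-state inconsistency at stitching boundaries.  These are
signal-level surrogates and are not calibrated to expert image-quality
scores.

## Study orchestration

`run_study()` re-enacts the two-cohort design on synthetic data: generate
two cohorts, compute metrics, select the irregular reference set, match
the second cohort, simulate both protocols on each matched pair's
reference curve (pairing the protocol contrast on an identical signal),
and summarize with medians and Mann-Whitney tests.  Per-curve generator
parameters are drawn from configurable ranges chosen to emulate adult
rest breathing: period 3–5.5 s (11–20 breaths/min), amplitude variability
from near-regular to strongly irregular (SD up to 0.35 of the mean),
pauses of 6–14 s in ~30% of curves, mild linear drift, 2% measurement
noise at 25 Hz.  Default problem sizes — 60 curves per cohort, 210 s per
curve, 192 mm field of view (10 spiral stations, 6 sequence positions) —
keep a full study run in the tens of seconds while covering the lower-lung
range where artifacts matter most.  Curve-specific child seeds are derived
from one master seed by a Lehmer-style integer hash, so outputs are
byte-identical across repeated runs and individual curves are reproducible
in isolation.  A pair whose curve violates a simulator precondition at an
unusual seed is recorded with a `skipped` status instead of aborting the
study.

## Rank statistics

`mann_whitney_u()` counts dominating pairs (ties count one half).  For
pooled sizes up to 12 without ties the two-sided p-value is exact by full
enumeration of all $\binom{n_x+n_y}{n_x}$ labelings, defined symmetrically
as $P(|U - \mu| \ge |u - \mu|)$; otherwise the normal approximation with
tie-corrected variance and continuity correction is used.  Two-sided
p-values are used throughout, as the cohort comparisons state no
direction.  `spearman_rho()` is the Pearson correlation of mid-ranks;
its p-value is deliberately not computed.

## Numerical choices and degenerate inputs

* Uniform sampling is enforced at a relative spacing tolerance of 1e-6;
  curve files are written with six decimals, making write→read→write
  byte-stable.
* Intervals are half-open `[start, end)` everywhere; times are seconds
  from the first sample.
* Ties in peak thinning keep the earlier peak; ties in selection and
  matching resolve by curve id.
* Constant traces, monotone ramps, too-few cycles, empty beam-on windows,
  too-small cohorts, and too-short signals raise classed errors
  (`zero_range`, `insufficient_cycles`, `empty_window`, `size_error`,
  `insufficient_signal`, …) rather than propagating NaNs.

## Known limitations

The simulators ignore reconstruction physics (no sinograms, no dose),
amplitude-based gating, and rotation-time adaptation; spiral binning is
phase-based only.  The double-structure proxy compares surrogate
amplitudes, not anatomy.  The synthetic generator's regularity classes are
parametric idealizations; conclusions about clinical breathing curves
require validation on real RPM/RGSC exports, which the column-mapping
reader can ingest but which ship with no public reference data.
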