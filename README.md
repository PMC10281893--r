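# breath4dct

Breathing-signal irregularity analysis and desk-scale simulation of the
two clinically used 4D CT acquisition strategies.

4D CT scans for radiotherapy planning of thoracic and abdominal tumors
reconstruct one image per breathing phase from projection data correlated
with a respiratory surrogate (RPM/RGSC-style camera traces).  When a
patient breathes irregularly — strong amplitude differences between
successive cycles, frequency variability, breathing pauses — conventional
retrospectively gated *spiral* scanning at a fixed low pitch produces
double-structure and interpolation artifacts, because the data acquired
for a couch position no longer cover every phase consistently.
Breathing-adapted *sequence* scanning instead keeps the beam on at each
couch position until real-time signal analysis confirms that a
representative breathing cycle has been captured.

`breath4dct` is for medical-physics researchers who want to study this
contrast quantitatively at the signal level, without clinical data or
image reconstruction:

* **Irregularity metrics.** After windowing a curve to its beam-on span,
  linear drift correction (OLS) and unit-range normalization, the package
  computes the sample SD of per-cycle peak-to-peak amplitudes
  (σ of the cycle excursions, dimensionless on the unit range) and the
  breathing pauses — inter-peak gaps ≥ 1.5 × the median cycle length.
* **Cohort construction.** Selection of the most irregular curves
  (top-15 by amplitude SD, top-10 by longest pause, disjoint) and greedy
  nearest-neighbour matching of a second cohort by the same statistics.
* **Acquisition simulation.** A timing model of low-pitch spiral 4D CT
  (couch speed `pitch × collimation / rotation time`, illumination window
  `rotation time / pitch`, retrospective phase binning) and of
  breathing-adapted sequence scanning (per-position beam-on until a cycle
  matches a learned reference within period/amplitude tolerances), with
  per-(position × phase) coverage and two artifact proxies: missing-cell
  counts and a double-structure score (motion-state inconsistency at
  adjacent positions).
* **Synthetic ground truth.** A seeded cos-power breathing generator with
  controllable period/amplitude variability, pauses, drift and noise,
  annotated with true peaks, cycles and pauses.
* **Rank statistics.** Self-contained two-sided Mann-Whitney U (exact by
  enumeration for small samples, tie-corrected normal approximation
  otherwise) and Spearman rank correlation.

## Worked example

Generate an irregular breather (strong amplitude variability plus a 9 s
pause), compute its irregularity metrics, and compare the two acquisition
protocols on the same curve:

```r
library(breath4dct)

spec <- synthetic_spec(duration_s = 210, period_mean_s = 4, period_sd_s = 0.4,
                       amp_sd = 0.3, noise_sd = 0.02,
                       pauses = list(c(12, 9)), seed = 7)
gen <- generate_signal(spec)

pp  <- preprocess_signal(gen$signal)
seg <- segment_cycles(pp, detect_inhalation_peaks(pp))
m   <- irregularity_metrics(seg, curve_id = gen$signal$curve_id)

cmp <- compare_protocols(gen$signal,
                         spiral_scan_config(fov_length_mm = 192),
                         sequence_scan_config(fov_length_mm = 192))
```

Output:

```
amplitude SD (unit range): 0.150 | longest pause: 13.6 s | mean cycle: 4.08 s
spiral   scan  55.6 s | duty 1.00 | missing phase cells  7 | double-structure 0.151
sequence scan 120.9 s | duty 0.84 | missing phase cells  0 | double-structure 0.133
```

Reading: the pause (13.6 s gap — the inserted 9 s hold plus the
interrupted cycle) outlasts the spiral protocol's 5.6 s illumination
window, so seven (position, phase) cells have no usable data and would
need interpolation; the sequence protocol simply dwells through the pause
(duty cycle 0.84, longer scan) and covers every phase, with lower
motion-state inconsistency at couch-position boundaries.

`run_study()` scales this to the full two-cohort design — generate two
60-curve cohorts, select the 25 most irregular reference curves, match
the second cohort, simulate both protocols per matched pair — and writes
deterministic JSON reports.

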