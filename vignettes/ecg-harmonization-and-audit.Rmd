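---
title: "Spectral harmonization and model auditing for 12-lead ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral harmonization and model auditing for 12-lead ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgkit)
```

## The problem

A deep model trained on one hospital's ECGs encounters, at another center,
the same physiology wrapped in a different acquisition signature: sub-1 Hz
baseline drift from patient movement and respiration, powerline tones at
50 or 60 Hz (and harmonics) with their strength depending on local mains
and shielding, and per-lead amplitude scales that differ between recorder
vendors and export pipelines. These signatures live almost entirely in the
power spectrum, which is why `ecgkit` harmonizes datasets in the frequency
domain and leaves the 1–30 Hz band — where the clinically meaningful
P-QRS-T morphology resides — as untouched as possible.

The package has two halves: the harmonization pipeline, and the audit
toolkit used to evaluate a multilabel classifier built on the harmonized
data (discrimination metrics with resampled confidence intervals, an
equalized-odds fairness audit, a membership-inference privacy attack, and
perturbation-based attribution).

## The harmonization model

Each stage is *conditional*: it runs only when its diagnostic fires, so a
dataset that is already clean passes through (nearly) unchanged, and
running the pipeline twice is a no-op the second time.

### Stage 1 — conditional high-pass

The trigger statistic per lead is the low-frequency excess
$E = \overline{\log_{10} P}_{(0,1)\,\mathrm{Hz}} -
     \overline{\log_{10} P}_{[1,30]\,\mathrm{Hz}}$,
and the stage fires when $E > 1$: one logarithmic unit of sub-1 Hz
enrichment relative to the clinical band. Being a log-ratio, $E$ is
invariant to the record's overall gain, so the trigger cannot be fooled by
amplitude differences. The filter is an order-4 Butterworth high-pass at
1 Hz applied forward–backward (zero phase), so the ST segment is not
skewed by group delay.

Two numerical choices matter here:

* **Welch resolution is decoupled between the two diagnostics.** Peak
  detection uses 2 s Hann segments with 50 % overlap (0.5 Hz bins, enough
  segment averaging for a stable local SD). The low-frequency trigger
  instead uses 5 s segments (0.2 Hz bins): with 0.5 Hz bins the open
  interval (0, 1) Hz holds a single bin sitting next to the heartbeat
  fundamental, and window leakage from that line alone can exceed one log
  unit — the trigger would fire on perfectly clean records. At 0.2 Hz
  resolution the band holds four bins and the statistic measures what it
  is meant to measure. Records shorter than the segment length raise an
  error asking for a smaller `segment_s`.
* **Edge handling of the zero-phase filter.** Forward–backward IIR
  filtering is exact only in the interior; at the record edges the filter
  state is wrong, and with a strong drift component (the synthetic
  stress-tests inject wander two orders of magnitude above the signal) the
  resulting transients are visible across seconds of signal and corrupt the
  amplitude-matching stage downstream. `apply_highpass` therefore extends
  each lead on both sides with autoregressive (Burg) forecasts — which
  continue drift *and* in-band oscillations smoothly across the boundary —
  runs each causal pass warm-started at the steady state for the boundary
  value, and discards the extensions. On a pure in-band tone the residual
  edge error is below $10^{-4}$ mV; on a 100 mV sub-band drift the residual
  is at the filter's stopband floor, uniformly across the record.

### Stage 2 — artifact-peak detection and LOESS flattening

For each candidate frequency (50 and 60 Hz and their harmonics below
Nyquist; the set is configurable), the detector compares the candidate's
log-power against the local baseline: mean and SD of per-bin log power in
a ±5 Hz window around the candidate, excluding the candidate's own ±1 Hz
so a peak cannot inflate its own reference statistics. A peak is declared
when the candidate statistic exceeds the local mean by `k_sd = 2` standard
deviations.

Three defaults shape the detector's operating point; all are exposed as
arguments:

* **The candidate statistic is the mean log-power over the exclusion-zone
  bins**, i.e. the bins a windowed tone's energy actually occupies, rather
  than a single bin. A single-bin statistic at 2 SD false-fires on roughly
  1 % of candidate tests per lead; with eight candidates and twelve leads
  that flags most clean records. Averaging over the leak width preserves
  the 2 SD rule while pushing the record-level false-positive rate far
  below it (measured: 0.5 % of 200 clean synthetic records, with
  sensitivity 1.0 on tones ≥ 10× background).
* **Detection is pooled across leads by default** (`pool_leads = TRUE`):
  mains interference is common-mode across electrodes, so the rule is
  evaluated once per record on the lead-averaged log spectrum and a
  detected peak is removed from every lead. Per-lead mode is available for
  genuinely lead-local artifacts.
* **Harmonics are gated on their fundamental**
  (`require_fundamental = TRUE`): a 120 Hz mains harmonic without 60 Hz
  interference is physically implausible, and the gate removes chance
  exceedances at harmonic candidates. Harmonic peaks carry a
  `harmonic_of` annotation.

Flattening is spectral surgery on the full-length FFT (not the Welch
estimate), so inversion is exact and bins outside the peak zones are
numerically unchanged: a local-linear LOESS curve is fitted to log-power
over the ±5 Hz neighborhood (peak ±1 Hz excluded), the peak bins'
magnitudes are replaced by the LOESS prediction, the original phase is
retained, and the signal is rebuilt by inverse FFT. Peaks reaching DC or
Nyquist are refused. Note the reconstruction's limit: the *original* noise
that the tone sat on is unrecoverable — the replaced band carries the
baseline's magnitude with the contaminated phase. This is irrelevant for
band power but is the reason the end-to-end clinical-band tolerance below
is 5 % rather than zero.

### Stage 3 — amplitude matching

The reference profile stores, per lead, the pooled (p1, p99) amplitude
percentiles of the reference dataset. Matching multiplies each lead by
`reference span / record span`. The map is idempotent and
scale-equivariant (`match(c·x) = match(x)`), so re-harmonizing produces
scale factors of exactly 1. "Amplitude range" is not a standard quantity;
the percentile span is this package's declared choice — percentiles ignore
rare spikes that a min–max range would chase, while still tracking the
R-wave envelope. Span estimation (in profiles and in matching alike)
excludes a 0.5 s guard interval at each record end: the earlier stages are
exact in the record interior, and whatever small residual they leave at
the very edges should not bias a statistic as tail-sensitive as a 99th
percentile. Flat (zero-span) leads are left unscaled with a warning
rather than failing the record.

### The decision log

`harmonize_record` returns a `harmonization_log` holding the per-lead
excess values, which leads were filtered, every removed peak, and the
scale factors, together with the configuration snapshot.
`replay_harmonization(input, log)` re-applies exactly those decisions and
reproduces the output bit-for-bit; the JSON serialization round-trips the
log at full double precision (replay after a round trip agrees to one
unit in the last place, the limit of decimal float serialization).

## The audit toolkit

**Metrics.** AUROC is the midrank (Mann–Whitney) estimator, exactly equal
to pair counting with half-credit ties; AUPRC is the tie-safe
average-precision step integral. The *overall* AUROC concatenates all
(record, label) cells into one vector pair — a micro view of global
performance. Confidence intervals subsample 70 % of records without
replacement, 1,000 iterations, and report the empirical 2.5/97.5
percentiles; "70 % bootstrap" is ambiguous in common usage, and
subsampling without replacement is the reading consistent with the
fairness protocol's wording, with a with-replacement flag provided.
Degenerate iterations (a single-class label in the subsample) are redrawn
up to 10 times so iteration counts stay exact. Resampling is at the
record level: cell-level resampling would break within-record correlation
across labels.

**DeLong.** Implemented from the structural components of the paired
Mann–Whitney statistics with the usual covariance estimate; identical
score vectors have zero variance and return p = 1 with a `degenerate`
flag instead of dividing by zero. The implementation is cross-checked in
the test suite against both `pROC::roc.test` and a 10,000-draw
permutation oracle. The pair-comparison step is O(n_pos × n_neg), sized
for evaluation sets, not millions of records. No multiple-testing
correction is applied across labels by default, mirroring the evaluation
protocol this toolkit implements; `stats::p.adjust` composes trivially
with the per-label outputs if a user wants it.

**Thresholds.** Per label, the threshold maximizing
(sensitivity + specificity)/2 over all unique scores (predict positive at
`score ≥ t`). Ties resolve to the midpoint of the lowest optimal interval,
which is deterministic and symmetric; thresholds are meant to be frozen on
a training set and applied unchanged everywhere else.

**Fairness.** Equalized odds asks whether TPR and FPR are balanced across
groups. Age is binned into under 55 / 55–75 / over 75, the 55 and 75
boundaries read inclusively into the middle group (the source convention
does not disambiguate exact boundary ages; this is the declared choice).
Rates are micro-averaged within groups (all cells pooled before the
ratio). Each of 1,000 iterations subsamples 70 % of records and computes
the mean absolute pairwise disparity; with two groups this is exactly
|rate_A − rate_B| per iteration. Iterations that lose a group or a
denominator are redrawn, never propagated as NaN. The report carries the
mean and the max over iterations for both TPR and FPR, since a summary
"difference < 0.01" can be read as either.

**Privacy.** The membership-inference attack labels logit rows by
membership, balances class sizes by subsampling the larger set (so 0.5 is
the true null AUROC), splits 80/20 stratified, fits a 50-tree random
forest, and reports evaluation-split AUROC plus normalized impurity
importances; `mia_repeated` aggregates over a predefined seed list (10 by
default). Raw logits and post-sigmoid probabilities are both accepted —
the attack is representation-agnostic. The t-SNE diagnostic embeds up to
10,000 sampled rows per set at perplexity 30 and scores membership
separation with the mean silhouette width — a diagnostic added by this
package to make "more separation, more re-identifiable" quantitative; the
silhouette is computed on a seeded subsample of at most 2,000 embedded
points because it needs an O(n²) distance matrix, while coordinates are
returned for every embedded point.

**Explainability.** LIME for multichannel 1-D signals: the record is tiled
into equal contiguous segments per lead (default 10 segments on a 10 s
record ≈ one beat per segment at resting heart rate), random binary masks
replace switched-off segments with a baseline (zero by default, lead-mean
optional), the black-box is scored on each perturbed record, and a
ridge-penalized weighted least squares surrogate (penalty 1e-6, intercept
unpenalized) is fitted in mask space with kernel weights
`exp(-d²/w²)`, `d` the mask's Euclidean (√Hamming) distance from the
unperturbed mask and `w = 0.25·√(n segments)`, the conventional LIME
width. Each label is analysed independently: the attribution reads only
the requested label's output, verified by a permutation property test.
Segment count, perturbation count, baseline, and kernel width are declared
heuristics, not inherited values.

## What the synthetic generators emulate — and what they do not

The pseudo-ECG is a quasi-periodic train of Gaussian bumps (P, Q, R, S, T
per beat) at 72 beats/min by default, with per-lead gain multipliers drawn
from [0.6, 1.4] and 0.02 mV white measurement noise, 12 leads, 10 s at
500 Hz. This reproduces what the pipeline actually depends on — energy
concentrated in 1–30 Hz, a harmonic comb at the beat rate, a noise floor
near the mains frequencies, realistic amplitude spans — with exact
knowledge of every injected contamination (the additive trace is stored
alongside the record, so tests can subtract it back out). The default
heart rate is deliberately not 60 bpm: a beat fundamental locked exactly
onto the 1 Hz filter cutoff and onto the Welch bin grid is a degenerate
alignment that no real recording exhibits, and it would make edge cases of
the estimator, not the method, dominate the tests.

It is *not* physiological simulation: no conduction model, no heart-rate
variability, no arrhythmia morphologies, no electrode-motion transients.
Consequently, passing tests demonstrate that the pipeline removes the
targeted contamination classes and preserves the clinical band on signals
with ECG-like spectra — not that it is robust to every artifact class in
clinical recordings.

The prediction-set generator draws, per cell, the binary outcome at the
group's prevalence and then a score from one of two Beta(2,2)-shaped
distributions on either side of 0.5, crossing 0.5 with probability equal
to the group's target TPR (positives) or FPR (negatives) — so thresholding
at 0.5 reproduces the designed confusion rates exactly in expectation, and
empirical rates converge at the usual √n rate. The logit generator draws
two Gaussian sets differing only by a configurable per-feature mean shift;
zero shift makes them exchangeable, the exact null of the membership
attack.

## Problem sizes and tolerances in the checks

The end-to-end suite and `scripts/acceptance.R` run at these scales,
chosen to make the Monte-Carlo noise floor comfortably smaller than each
tolerance: 200 contaminated and 200 clean records for the pipeline checks
(pass rate must be 100 %, clean triggers 0 %, peak false positives < 5 %
of records, 2–30 Hz band power within 5 % of the stored clean oracle); 100
random sets against brute-force oracles for thresholds (exact) and AUROC
(exact, including ties); a 200-record paired comparison against a
10,000-draw permutation test (agreement within 0.05); fairness at 20,000
records × 77 labels — the multilabel scale at which micro-averaging
operates — recovering a designed 0.2 TPR gap within ±0.02 and an
identical-groups null below 0.005; membership inference at 1,000 + 1,000
rows × 8 logits, 20 null replicates (mean attack AUROC within
[0.45, 0.55]) and a 10 SD single-feature shift (mean AUROC > 0.95, shifted
feature ranked first); LIME on a 2-lead, 100 Hz fixture with 100 seeds
(top-segment recovery ≥ 95 %) and Spearman ρ > 0.9 against the true
linear coefficients at 1,000 perturbations. All stochastic stages take
explicit seeds and are bit-reproducible under them.

## Known limitations

* Flattening substitutes the LOESS baseline for the original spectral
  content under the peak; the true signal in the contaminated ±1 Hz is not
  recoverable.
* The DeLong implementation's O(n_pos × n_neg) pair comparison is not
  suited to very large evaluation sets.
* The low-frequency trigger needs records of at least the trigger's
  segment length (5 s by default).
* WFDB support covers format 16 with gain/baseline conversion — enough to
  round-trip this package's own records and plain PhysioNet-style files —
  not the full format zoo (multi-segment records, other sample formats).
* The fairness audit measures disparity; it implements no mitigation.
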