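---
title: "Methods: seizure detection, burden statistics and TRAP enrichment filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seizure detection, burden statistics and TRAP enrichment filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srseize)
```

# Scope

`srseize` implements the quantitative chain used to characterise
spontaneous recurrent seizures (SRSs) in the intrahippocampal kainate
model of mesial temporal lobe epilepsy, together with the
transcriptomic filter chain used to nominate astrocyte-enriched
candidate genes from TRAP/RiboTag RNA-seq:

1. amplitude-threshold SRS detection from single-channel LFP
   recordings and the derived burden metrics (frequency, duration,
   cumulative duration);
2. the bespoke statistics used around those metrics — a pooled
   bootstrap-resampling test for differences in group means, a
   two-sample Kolmogorov–Smirnov (KS) comparison of event-duration
   distributions, and an extra sum-of-squares F test for nested
   stimulus–response curve fits;
3. the astrocyte-enrichment differential-expression filters (FPKM,
   fold-change and adjusted-p thresholds, IP/input enrichment, top-k
   ranking) applied to expression tables;
4. seeded synthetic-data generators for all of the above, so that every
   stage is testable without any recording or sequencing data.

Upstream model fitting (read alignment, edgeR/limma-voom) is out of
scope by design: the per-gene log2 fold changes and adjusted p-values
are *inputs* to the filter chain, which is why the synthetic statistics
table is truth-driven rather than fitted.

# The detection model

## Definition

An SRS is operationalised as activity in the high-pass filtered LFP
whose amplitude exceeds 3 × the SD of the baseline signal and that
lasts strictly longer than 10 s. The "faster than 5 Hz" clause of the
seizure definition is implemented by the 5 Hz high-pass itself: slower
activity is removed before the amplitude criterion is applied, and no
separate spectral test is run. All four constants are exposed in
`detection_params()`.

## Filtering

The high-pass filter is a 4th-order Butterworth applied
forward–backward (`highpass_filter()`), so the effective magnitude
response is the squared single-pass response and the phase response is
zero — onset timestamps are not shifted by the filter. The IIR passes
run through C-level recursive filtering and are validated in the test
suite against both `signal::filter()` (exact agreement) and the
analytic Butterworth magnitude response.

## The amplitude criterion

The published rule does not state how "amplitude … that lasted" is
operationalised (envelope, RMS window, or crossing density). A raw
per-sample threshold on the rectified signal cannot be used as-is:
Gaussian background exceeds 3 × SD roughly 5 times per second at
2 kHz, so any gap-merging rule long enough to bridge the sub-threshold
troughs of a genuine 8 Hz discharge would also chain background
excursions into arbitrarily long false events. We therefore threshold
a *peak-scaled moving-RMS envelope* (`amplitude_envelope()`): the RMS
of the filtered signal over a centred 0.5 s window, multiplied by
√2. For a sustained sinusoidal discharge this envelope equals the peak
amplitude (so the 3 × SD criterion keeps its published meaning), while
for Gaussian background it concentrates tightly around √2 × SD ≈
1.41 × SD, far below threshold — background alone never triggers.
Supra-threshold runs separated by at most `merge_gap_s` (default 1 s,
about five cycles at the 5 Hz cutoff) of sub-threshold samples are
merged, and runs lasting strictly more than `min_duration_s` are
reported. Intervals are half-open `[onset, offset)` in seconds from
recording start, at one-sample resolution.

The detector is checked two ways: against a naive per-sample scan
oracle on noise-free signals (exact interval equality), and against
the simulator's ground truth on noisy recordings (recall = precision
= 1 with onset/offset errors below 1 s at the study's conditions; see
the acceptance tests).

## Baseline SD

The published procedure has a skilled experimenter select seizure-free
baseline stretches manually. `estimate_baseline_sd()` keeps that as
*manual mode* (a list of `[start, end)` intervals; the estimate is the
sample SD over their union, requiring at least 10 s of material) and
adds an *automatic mode* for unattended runs: the recording is cut
into 10 s windows, and the estimate is the median per-window SD among
the windows at or below the 0.1 quantile of window SDs. The quietest
decile stands in for the expert's choice; on a recording whose seizure
burden is below ~90% this selects seizure-free material by
construction. A constant (zero-SD) baseline raises an error rather
than propagating a zero threshold.

# Burden metrics

`seizure_metrics()` reports event count, frequency in events/hour
(`n / (duration/3600)`), the per-event durations and their sum
(cumulative time in seizures). Events must be disjoint and inside the
recording; half-open intervals make cumulative sums exact under
concatenation.

# Statistics

## Pooled resampling test

The test pools both groups; each of 10,000 iterations draws two
pseudo-groups of the original sizes from the pool *with replacement*
and records their mean difference; the null is rejected when the
observed mean difference lies outside the central two-sided 95%
percentile interval of that resampling distribution
(`resampling_mean_diff_test()`). Two readings of the published
procedure were open:

* *with vs without replacement* — the procedure is named a bootstrap,
  so with-replacement is the default; `mode = "permutation"` reshuffles
  the pool without replacement instead (the two differ at small n);
* *"true difference in means"* — read as the observed between-group
  mean difference;
* *hierarchical structure* — per-animal values are resampled flat; no
  within-animal resampling is attempted.

The test's operating characteristics are measured, not assumed: under
a null with the study's group sizes (9 vs 5) the interval covers the
observed difference in ~95% of replicates (the acceptance suite runs
1000 replicates and requires 95 ± 2 percentage points), and power is
monotone in the mean shift.

## Kolmogorov–Smirnov comparison

`ks_two_sample()` computes D as the supremum of the absolute ECDF
difference over pooled points (right-continuous ECDFs; ties handled by
evaluating at the end of each tied run) and the two-sided asymptotic
p-value from the Kolmogorov tail series at
λ = √(n₁n₂/(n₁+n₂))·D, truncated when terms fall below 1e-12. The
statistic is verified against a double-loop brute force and the stock
`stats::ks.test()`; the asymptotic p is verified to stay within a
factor of two of the exact enumeration p at n₁ = n₂ = 5. At the
published scale (D = 0.15 with 778 vs 326 events) the asymptotic tail
is of order 1e-5, matching the printed magnitude.

## Extra sum-of-squares F test

`extra_ss_f_test()` compares one shared curve against separate
per-group curves: F = ((SS_pooled − SS_sep)/(df_pooled − df_sep)) /
(SS_sep/df_sep), with p from the F distribution. The published
analysis does not name the fitted model, so two are offered: a
3-parameter logistic (`sigmoid3`, the natural shape for
stimulus–response curves, fitted by Levenberg–Marquardt) and a
`quadratic` (an exact linear fit, used for the null-calibration
simulations where fit convergence must not contaminate the measured
rejection rate). The printed degrees of freedom of the original
analysis depend on an unstated data layout and are not reproduced.
Duplicated groups give F = 0 and p = 1 by construction; under the null
the p-values are uniform (checked by a goodness-of-fit test on 500
simulated nulls).

# The DEG filter chain

The filters follow the published wording verbatim, including boundary
semantics:

| filter | rule | boundary |
|---|---|---|
| expressed | FPKM > 1 in all comparison samples | 1.0 excluded |
| DEG | \|log2FC\| ≥ 1 and adj. p < 0.05 | log2FC = 1.0 included, p = 0.05 excluded |
| astrocyte-enriched | IP/input mean-FPKM ratio > 2 | 2.0 excluded |

Where the figure caption uses "IP/input ≥ 2" the Methods text's strict
"more than 2-fold" wins; the comparator is a parameter
(`comparator = ">="`) for the caption convention. "All comparison
samples" is read as the IP samples (the later, more specific wording);
passing both fraction tables to `expressed_genes()` screens on all
samples instead. The IP/input ratio uses the mean FPKM across samples
within each fraction — IP and input libraries come from the same
animals but are not pairable per-sample, and at n = 3 the mean is the
robust choice. A zero input mean with non-zero IP mean yields an
infinite ratio (enriched) with a warning; an optional pseudocount
damps this, and the upstream FPKM floor makes the case rare.
`rank_top_degs()` orders by |log2FC| with deterministic tie-breaks
(ascending adjusted p, then gene id). `estimate_release_concentration()`
is the worked arithmetic that scales a total tissue concentration
range by an assumed release fraction (5% of content, by analogy with
astrocytic BDNF release): 370–560 ng/mL × 0.05 = 18.5–28 ng/mL.

# Synthetic data

## LFP

`simulate_lfp()` adds sinusoidal discharges to background noise. The
event waveform is a sinusoid at the configured dominant frequency
under a trapezoidal envelope with 0.5 s linear ramps — the simplest
shape that is "sustained, rhythmic and high-amplitude" — with plateau
amplitude `event_amplitude_factor × baseline_sd` and randomised phase.
Event counts are Poisson at the configured rate; placements are
uniform with rejection of overlaps, of positions within twice the
minimum duration of the recording edges (no truncated events), and of
gaps below `min_gap_s` (default 5 s, a realistic inter-ictal
separation that also keeps distinct truth events from being merged by
the detector's 1 s gap rule). Placement failure after bounded retries
raises an error. Defaults describe the recordings the detector
targets: 1 h at 2 kHz, 20 events/h, 15–60 s durations, amplitude
factor 5, 8 Hz. Background is white Gaussian by default; AR(1) and
1/f ("pink", spectral synthesis) variants exist so that tests can
confirm the baseline logic does not depend on spectral colour.

What the simulator does *not* emulate: spike-wave morphology,
inter-event clustering (only a rate parameter is exposed, as the
inter-event structure of SRSs is uncharacterised), electrode
artifacts, drift, or multi-channel volume conduction. Perfect
recall/precision on these recordings therefore demonstrates the
detector logic, not performance on real LFPs — the manual-baseline
mode and the exposed parameters are the knobs a practitioner would
retune on real data.

## Expression tables

`simulate_trap_tables()` draws per-gene baseline mean FPKMs
log-normally, multiplies IP-fraction means by the planted enrichment
ratio, multiplies *both* fractions' KA means by the planted fold
change (a tissue-level change of an astrocyte-expressed transcript —
this keeps every gene's expected IP/input ratio equal to its planted
ratio, so enrichment recovery is well-defined), and applies
multiplicative log-normal noise with a configured CV (default 0.1,
typical for FPKM replicates). Planted DEG baselines are floored at
FPKM 10 so planted truth always survives the expression filter. The
statistics table passes planted log2 fold changes through exactly and
assigns adjusted p < 0.05 to planted DEGs and ≥ 0.05 otherwise.

# Numerical choices

* Fixture format: little-endian float32 + JSON sidecar — lossless for
  simulated data, compact, byte-stable round trips. EDF export uses
  one data record and a symmetric physical range, so round trips are
  exact to one 16-bit quantisation step; the declared physical
  dimension is the only rescaling the loader ever applies.
* Zero-phase filtering uses zero initial conditions; edge transients
  decay within well under a second at a 5 Hz cutoff, and the
  simulator's edge margins keep events away from them.
* `group_runs()` counts a gap as the number of sub-threshold samples
  between crossings, so `merge_gap_s = 0` merges exactly adjacent
  samples and nothing else.
* The F statistic is clamped at zero against floating-point
  cancellation when the two fits coincide.
* The Kolmogorov series is truncated at 1e-12; p is clamped into
  (0, 1].
* Percentile intervals use `quantile()`'s default type; with 10,000
  resamples the choice of quantile type moves the bounds by far less
  than their Monte-Carlo error.

# Problem sizes

The validation suites run at: 1000 null replicates × 10,000 resamples
(interval coverage); 50 recordings of 1 h at 2 kHz (detector
recall/precision); 500 simulations each for the null rejection rates
of the F and resampling tests; 50 seeds × 5000 genes × 50 planted
DEGs (filter-chain recovery); 100 seeds for Monte-Carlo enrichment
recovery. These sizes give Monte-Carlo standard errors comfortably
below the tolerances being asserted.

# Known limitations

* The detector is single-channel and does no artifact rejection;
  movement artifacts in real LFPs can exceed 3 × SD and would need
  manual baseline selection or pre-cleaning.
* The automatic baseline assumes at least a decile of quiet windows;
  recordings that are nearly continuous seizure need manual intervals.
* The asymptotic KS p is conservative or anticonservative by up to a
  factor ~2 at very small n; exact enumeration is preferable below
  n ≈ 10 per group.
* The `sigmoid3` F test requires enough stimulus range to constrain
  the plateau; degenerate designs raise explicit fit errors rather
  than returning silently wrong statistics.
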