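---
title: "Microstate analysis of neonatal EEG: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate analysis of neonatal EEG: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoms)
```

## The problem

EEG of preterm neonates changes rapidly with maturation between roughly 26
and 44 weeks post-menstrual age (PMA). Microstate analysis models the
multichannel EEG as a sequence of brief (~100-300 ms) quasi-stable scalp
topographies ("microstate maps"). The dynamics of that sequence — how long
each map lives (duration, s), how often maps recur (occurrence, Hz), what
fraction of time each covers (coverage), how much topographic variance the
maps explain (global explained variance, GEV), whether transitions between
maps are random (syntax), and how persistent the sequence is over long lags
(Hurst exponent) — provide a compact description of global cortical dynamics
that does not assume stationarity or pick channels and frequency bands in
advance.

`neoms` implements the full pipeline for 9-channel neonatal montages
(Fp1, Fp2, C3, C4, T3, T4, O1, O2, Cz at 250 Hz), along with a synthetic
cohort generator with known ground truth, so that every stage can be
validated quantitatively without access to clinical recordings.

## Preprocessing

Each epoch is (1) bandpass filtered, (2) resampled, (3) re-referenced to the
common average. Defaults: 0.2-25 Hz band, 7th-order Butterworth, resampling
to 100 Hz, 5-minute epochs. The high-pass edge of 0.2 Hz preserves the delta
band (0.5-4 Hz) that dominates neonatal EEG; the low-pass edge of 25 Hz
removes muscle and line components.

Numerical choices worth knowing about:

* **Second-order sections.** A 7th-order bandpass has 14 poles; at 250 Hz
  with a 0.2 Hz edge the poles sit at radius ~0.999 and the polynomial
  transfer function is numerically unusable (we measured gains of ~1e75 from
  a naive implementation). The filter is therefore designed analytically
  (analog Butterworth prototype, lowpass-to-bandpass transform, bilinear
  transform) and applied as a cascade of biquads.
* **Zero phase.** Filtering runs forward and backward. Microstate boundaries
  are timing-sensitive; a causal filter's group delay would shift every
  label. The magnitude order consequently doubles; the design order stays 7.
* **Edge handling.** Odd-reflection padding of about three time constants of
  the slowest pole suppresses start-up transients.
* **Resampling** is performed in the frequency domain (band-limited sinc
  interpolation at the exact rational ratio, reflection-padded). A 5 Hz test
  tone resampled 250 to 100 Hz reconstructs with interior relative RMS error
  around 1e-7.

Re-referencing is a per-sample linear map and commutes with the two
channel-wise linear steps to numerical precision; the test suite asserts
this.

## Map identification

Only samples at peaks of global field power (GFP, the per-sample standard
deviation across channels) enter clustering: they are the moments of highest
topographic signal-to-noise. A peak is a strict local maximum with a
plateau credited to its onset (the definition is a package choice; any
deterministic rule works, and endpoints are excluded).

The **modified k-means** clusterer is polarity-invariant: a map and its
negation are the same microstate. Assignment maximises the squared spatial
correlation; the map update is the first principal eigenvector of the
cluster's scatter matrix. Defaults: 20 restarts, tolerance 1e-6 on the
relative change of explained variance, at most 500 iterations; an empty
cluster is reseeded from the worst-fit sample. Maps are stored zero-mean,
unit-norm, with the largest-loading channel positive (a display convention
only — every comparison in the package takes absolute correlations).

**Choosing k.** The Krzanowski-Lai (KL) criterion is applied to the
dispersion curve W(k) for k = 3..15. We define W(k) as the trace of the
within-cluster scatter under polarity-invariant projection — equivalently
the GFP-weighted variance left unexplained by the k maps, the exact quantity
the clustering minimises. (An alternative based on mean pairwise
within-cluster distances was evaluated and rejected: because restarts do not
optimise it directly, its tail fluctuates and the KL ratio — which divides
successive differences — amplifies that noise into spurious maxima at large
k.) With differences
`DIFF(k) = (k-1)^(2/m) W(k-1) - k^(2/m) W(k)` and effective dimension
`m = channels - 1` (the common average removes one dimension),
`KL(k) = |DIFF(k)| / |DIFF(k+1)|` and k is chosen as the argmax over the
search range, restricted to k with `DIFF(k) > 0`. The restriction is part of
what "elbow" means — at an elbow the weighted dispersion still drops —
and it guards the ratio against a known pathology: past the true cluster
count, successive DIFF values fluctuate around zero, and dividing by a
near-zero `DIFF(k+1)` otherwise produces spurious maxima at large k (on
calibrated synthetic epochs the unrestricted argmax lands at k = 13..15 in
roughly a fifth of epochs; the restricted rule selected the generating
k = 4 in 40 of 40). Clustering is also run at k = 2 and k = 16 so that
every k in 3..15 has a defined KL value. The KL scan uses 10 restarts per k (half the
single-fit default): the scan is 15 fits, and the objective-based dispersion
curve is insensitive to the extra restarts.

Group-level maps pool the individual maps of all epochs in an age x sleep
cell and re-cluster them. Map order is matched across cells by exhaustive
search over the k! permutations, maximising the mean polarity-invariant
correlation with the reference cell.

## Backfitting and metrics

The chosen maps are backfitted to the entire continuous epoch: each sample
takes the map with maximal |spatial correlation|, ties to the lowest index,
zero-variance samples inheriting the previous label. Temporal smoothing
follows the classic segmentation-smoothing scheme: each sample's normalised
residual is discounted by `penalty` times the number of same-labelled
neighbours within a one-sided window of `round(window_ms * fs / 1000)`
samples (3 samples at the default 30 ms and 100 Hz), iterated to a fixed
point. Penalty 0 returns the input labels untouched. GEV is computed on the
smoothed labels — they are the labels every metric uses.

From the run-length encoding: per-map duration (mean run length / fs),
occurrence (runs per second of epoch), coverage (fraction of samples);
overall mean duration and occurrence pool all runs regardless of label. The
identities `coverage = occurrence x duration` per map and
`1 = overall occurrence x overall duration` hold exactly by construction.
Boundary runs truncated by the epoch edges are included: at 5-minute epochs
with ~0.2 s runs the bias is below 0.2%, and the rule is deterministic. The
occurrence denominator is the full epoch length (epochs carry no missing
samples).

## Syntax

Observed transition probabilities count consecutive run labels
(self-transitions cannot occur). The chance expectation for A to B is
`q(B) / (1 - q(A))` where q is the run-label share — the next label drawn
from the label distribution conditioned on differing from the current one.
The randomness test computes the chi-square distance between observed and
expected transition *counts* and compares it against shuffles of the run
labels that preserve the multiset and the no-adjacent-repeat structure
(shuffle, then repair collisions by targeted swaps; near-infeasible
multisets fall back to an exact sequential construction). The p-value uses
the add-one estimator `(1 + #{null >= obs}) / (1 + n_perm)`, whose floor at
the default 5000 permutations is 1/5001 — just under 0.0002. Group-level
transition effects are paired t-tests of observed minus expected per
transition across the epochs of a cell, Benjamini-Hochberg corrected across
the k(k-1) ordered transitions within the cell, with direction flags and
strong/weak thresholds at 0.05 and 0.1.

## Topography comparison and long-range dependence

**TANOVA.** Two maps are compared with |spatial correlation| as effect
size; the null permutes the channel order of one map (permuting one already
destroys spatial alignment; absolute correlation matches the package-wide
polarity convention). Significance means *similarity*. The add-one
estimator applies.

**Hurst exponent.** A categorical sequence has no canonical random walk, so
each of the `2^(k-1) - 1` nontrivial bipartitions of the labels is embedded
as a +/-1 series; order-1 detrended fluctuation analysis is applied to each
cumulative-sum walk over ~15 log-spaced box sizes in `[10, length/4]`, and H
is the mean log-log slope across bipartitions. The estimator is exactly
invariant under relabelling. Note that at box sizes comparable to the mean
run length the walk is locally ballistic, so sequences with long runs carry
an upward bias relative to their run-level persistence; this affects real
and synthetic sequences alike and does not disturb ordering or trend
analyses, which is what the estimator is used for.

## The synthetic cohort

No public neonatal dataset accompanies this problem, so the generator *is*
the study design:

* **Maps**: random zero-mean unit-norm topographies with pairwise
  |correlation| at most 0.6 (resampled until separated). No dipole forward
  model: the analysis is reference- and geometry-agnostic, and only map
  distinguishability matters.
* **Semi-Markov sequences**: geometric run lengths with mean
  `fs * duration / 1000` samples and run labels from a configurable
  transition matrix — the dial for duration, occurrence and syntax (its
  renewal structure makes H = 1/2).
* **Long-range-dependent sequences**: fractional Gaussian noise (exact
  Davies-Harte circulant embedding) thresholded at empirical quantiles into
  equiprobable labels — the dial for the Hurst exponent.
* **Forward model**: active map times a delta-band (0.5-4 Hz) activation
  waveform plus spatially white Gaussian noise, average-referenced. The
  default signal-to-noise ratio (0.35) was calibrated once, by bisection, so
  that the full default pipeline attains a mean GEV near 0.70 — the level
  reported for neonatal recordings — and is not revisited.
* **Cohort**: 48 subjects by default, gestational ages 24.6-32.0 weeks,
  2-4 recordings each at distinct PMA age groups (≤31, 32-33, 34-36, ≥37
  weeks — at most one recording per subject per group), one QS and one NQS
  epoch per recording. Ground-truth mean duration falls linearly with PMA
  (275 ms at 30 weeks, -12.5 ms/week, clipped to 100-400 ms, per-subject
  random intercepts of SD 15 ms), emulating the published 250-300 ms at 30
  weeks falling to 150-200 ms after 37 weeks. The Hurst target falls
  linearly too, faster in quiet sleep (0.72 - 0.008/week from 26 weeks) than
  in non-quiet sleep (0.66 - 0.003/week), mirroring the reported asymmetry
  between sleep states. The sleep-state effect on duration defaults to 0:
  the literature reports small and direction-ambiguous differences, so the
  simulator leaves the effect as an explicit configuration parameter rather
  than encoding a sign.
* Since one sequence cannot obey both the geometric-run and the
  fGn-threshold law, cohort epochs use a hybrid: run-level labels come from
  collapsing a thresholded fGn (carrying persistence), run lengths are
  geometric (carrying the duration law).

What the generator does *not* emulate: artefacts, volume-conduction
geometry, non-stationary background (trace alternant), wakefulness as
distinct from active sleep. Passing the validation suite therefore shows
the pipeline recovers known dynamics from realistic noise levels — not that
clinical preprocessing decisions (artefact rejection, sleep staging) are
solved; those stay caller-provided inputs.

## Validation battery and problem sizes

The package's acceptance checks (mirrored in `scripts/acceptance.R` and
`tests/testthat/test-acceptance.R`) recompute, from scratch:

* metric identities (coverage conservation) on backfitted epochs;
* KL selection of k = 4 across 20 full-length (300 s) default epochs;
* mean GEV of the 4-map backfit across those epochs (bracket 0.66-0.73);
* recovery of every generating map at |correlation| ≥ 0.95;
* type-I error of the syntax test (1000 replicates of ~120 i.i.d. runs at
  199 permutations each) and uniformity of the TANOVA null (1000
  replicates, Kolmogorov-Smirnov distance);
* Hurst calibration at the memoryless point and ordering of H targets 0.6
  vs 0.9 over 20 paired sequences;
* maturation-trend recovery on a cohort of 32 subjects with 60 s epochs —
  sizes chosen so the whole battery runs in minutes on one core while
  leaving the per-epoch sample counts (6000 samples, ~350 runs) large
  enough that per-epoch estimation noise is a small fraction of the
  designed PMA effect;
* equality of the clustering objective with an exhaustive-assignment oracle
  at small n, and of map matching with the brute-force k! maximiser.

## Known limitations

* Recovered absolute durations are compressed at realistic noise levels
  (noise splits long runs more often than short ones), so duration is best
  treated as a relative, not absolute, measure; orderings and trends are
  preserved, and the trend tests validate exactly that.
* The KL criterion is applied per epoch; on real data the dispersion curve
  is noisier and a fixed k (the default, k = 4, with the per-epoch KL value
  reported) keeps metric tables comparable across epochs.
* Mixed-effects modelling of the metric tables is out of scope by design:
  the package exports the tidy long-format table
  (`metrics_long_table()`) that such models consume, and reports Pearson
  correlations with PMA as the in-package association measure.
* The EDF reader/writer covers standard 16-bit EDF with equal per-channel
  rates — enough for round-tripping epochs, not a general EDF+ library.
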