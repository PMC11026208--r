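# neoms — microstate analysis of neonatal EEG maturation

`neoms` is an R package for EEG **microstate analysis** of preterm neonatal
recordings. Microstate analysis models multichannel EEG as a sequence of
brief (~100–300 ms) quasi-stable scalp topographies ("microstate maps") and
summarises global cortical dynamics through the statistics of that
sequence. In preterm neonates these statistics track brain maturation:
microstate duration falls and occurrence rises with post-menstrual age
(PMA), and the long-range temporal dependence (Hurst exponent) of the
sequence declines, especially in quiet sleep.

The package is aimed at researchers analysing 9-channel neonatal montages
(Fp1, Fp2, C3, C4, T3, T4, O1, O2, Cz; native 250 Hz) and at anyone who
needs a fully tested, ground-truth-validated microstate pipeline.

## What it computes

Given 5-minute artefact-free epochs labelled quiet sleep (QS) or non-quiet
sleep (NQS):

1. **Preprocessing** — zero-phase 7th-order Butterworth bandpass
   (0.2–25 Hz), resampling to 100 Hz, common-average re-referencing.
2. **Map identification** — polarity-invariant modified k-means on the
   topographies at global field power (GFP) peaks,

   `GFP(t) = sd over channels of v(t)`,

   with the number of maps k chosen by the Krzanowski–Lai criterion on the
   within-cluster dispersion W(k) over k = 3..15:

   `DIFF(k) = (k−1)^(2/m) W(k−1) − k^(2/m) W(k)`, `KL(k) = |DIFF(k)| / |DIFF(k+1)|`.

3. **Backfitting** — per-sample assignment to the map with maximal
   |spatial correlation|, temporal smoothing (30 ms window, penalty 1), and
   microstate metrics: per-map duration (s), occurrence (Hz), coverage,
   global explained variance

   `GEV = Σ_t (GFP(t)·corr(v_t, map_label(t)))² / Σ_t GFP(t)²`.

4. **Syntax** — observed vs expected transition probabilities
   (`E(A→B) = q(B)/(1−q(A))`), a randomized chi-square test of sequence
   randomness (5000 shuffles, add-one p-value), and paired per-transition
   tests with Benjamini–Hochberg correction.
5. **Topography and maturation statistics** — TANOVA channel-permutation
   tests of map similarity, Hurst exponents of the label sequence via
   detrended fluctuation analysis over all label bipartitions, and Pearson
   associations of each metric with PMA per sleep state.
6. **Synthetic cohort generator** — a first-class, tested module producing
   9-channel delta-dominant EEG from known microstate processes (geometric
   run lengths, thresholded fractional Gaussian noise for long-range
   dependence) across a preterm cohort design, so the entire pipeline is
   validated against ground truth.

## Worked example

```r
library(neoms)

# a small synthetic cohort: 8 subjects, 60 s epochs, QS + NQS per recording
cohort <- generate_cohort(cohort_spec(n_subjects = 8, epoch_s = 60), seed = 42)
cfg    <- analysis_config(n_restarts = 10, n_perm = 500, seed = 42)
ind    <- run_individual_analysis(cohort, cfg)

ind$epochs[1:4, c("subject_id", "pma_weeks", "sleep_state",
                  "mean_duration_s", "mean_occurrence_hz", "gev", "hurst")]
#> # A tibble: 4 × 7
#>   subject_id pma_weeks sleep_state mean_duration_s mean_occurrence_hz   gev
#>   <chr>          <dbl> <chr>                 <dbl>              <dbl> <dbl>
#> 1 S01             30.9 QS                    0.161               6.22 0.712
#> 2 S01             30.9 NQS                   0.159               6.28 0.701
#> 3 S01             33.1 QS                    0.160               6.27 0.686
#> 4 S01             33.1 NQS                   0.176               5.67 0.698

as.data.frame(ind$associations)
#>   sleep_state             metric     r       p  n   slope
#> 1         NQS              hurst -0.88 3.3e-07 20 -0.0081
#> 2         NQS    mean_duration_s -0.86 1.0e-06 20 -0.0036
#> 3         NQS mean_occurrence_hz  0.89 1.5e-07 20  0.1967
#> 4          QS              hurst -0.87 4.6e-07 20 -0.0102
#> 5          QS    mean_duration_s -0.82 9.2e-06 20 -0.0039
#> 6          QS mean_occurrence_hz  0.87 7.7e-07 20  0.2062
```

Each epoch row reports the overall mean microstate duration (~0.16 s here,
as designed for ~31 weeks PMA), occurrence (≈ 1/duration), the fraction of
GFP-weighted variance the four maps explain (`gev` ≈ 0.70), and the Hurst
exponent. The association table shows the maturation trends the cohort was
designed with: duration falls with PMA (r ≈ −0.8), occurrence rises, and
the Hurst exponent declines. `run_group_analysis()` runs the group-level
track (group maps per age × sleep cell, per-map metrics, syntax and TANOVA
tests); `metrics_long_table()` exports the tidy table a mixed-effects model
would consume.

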