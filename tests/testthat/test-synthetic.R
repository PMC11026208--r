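# Ground-truth generators: maps, label sequences, forward model, cohort.

test_that("generated maps are zero-mean, unit-norm, separated, deterministic", {
  m <- generate_maps(4, 9, seed = 1)
  expect_lt(max(abs(rowMeans(m$maps))), 1e-12)
  expect_equal(unname(sqrt(rowSums(m$maps^2))), rep(1, 4), tolerance = 1e-12)
  C <- abs(tcrossprod(m$maps))
  expect_lte(max(C[upper.tri(C)]), 0.6)
  m2 <- generate_maps(4, 9, seed = 1)
  expect_identical(m$maps, m2$maps)
  # two average-referenced channels span one dimension: infeasible
  expect_error(generate_maps(2, 2, seed = 3), "could not draw")
})

test_that("semi-Markov run lengths hit the configured geometric mean", {
  cfg <- ground_truth_config(mean_duration_ms = 200)   # 50 samples at 250 Hz
  for (seed in 1:5) {
    lab <- sample_label_sequence(cfg, 75000, seed = seed)
    ml <- mean(segment_runs(lab)$length)
    expect_gt(ml, 47.5); expect_lt(ml, 52.5)
  }
  one <- sample_label_sequence(cfg, 1, seed = 1)
  expect_identical(length(one$labels), 1L)
})

test_that("uniform transition matrices yield uniform observed transitions", {
  cfg <- ground_truth_config(mean_duration_ms = 40)
  lab <- sample_label_sequence(cfg, 60000, seed = 2)
  O <- observed_transitions(segment_runs(lab), 4)
  off <- O[row(O) != col(O)]
  expect_true(all(abs(off - 1 / 3) < 0.05))
})

test_that("LRD sequences have equiprobable labels and H=0.5 recovers", {
  cfg <- ground_truth_config(hurst_target = 0.5)
  lab <- sample_lrd_label_sequence(cfg, 30000, seed = 3)
  freq <- tabulate(lab$labels, 4) / 30000
  expect_true(all(abs(freq - 0.25) < 0.02))
  h <- hurst_dfa(lab)
  expect_gt(h, 0.45); expect_lt(h, 0.55)
  expect_error(ground_truth_config(hurst_target = 1.0), "hurst_target")
  expect_error(ground_truth_config(hurst_target = 0.3), "hurst_target")
})

test_that("the noiseless forward model reproduces its maps at GFP peaks", {
  cfg <- ground_truth_config(snr = Inf, epoch_s = 20)
  maps <- generate_maps(4, 9, seed = 4)
  lab <- sample_label_sequence(cfg, 5000, seed = 5)
  ep <- synthesize_epoch(maps, lab, cfg, seed = 6)
  g <- global_field_power(ep)
  pk <- gfp_peaks(g)
  r <- vapply(pk, function(i) {
    spatial_correlation(ep$data[, i], maps$maps[lab$labels[i], ])
  }, numeric(1))
  expect_true(all(r > 1 - 1e-6))
  # determinism
  ep2 <- synthesize_epoch(maps, lab, cfg, seed = 6)
  expect_identical(ep$data, ep2$data)
})

test_that("epoch synthesis respects the configured signal-to-noise ratio", {
  cfg_hi <- ground_truth_config(snr = 100, epoch_s = 20)
  cfg_lo <- ground_truth_config(snr = 0.1, epoch_s = 20)
  maps <- generate_maps(4, 9, seed = 7)
  lab <- sample_label_sequence(cfg_hi, 5000, seed = 8)
  gev_of <- function(cfg) {
    ep <- synthesize_epoch(maps, lab, cfg, seed = 9)
    compute_gev(ep, maps, lab$labels)
  }
  expect_gt(gev_of(cfg_hi), 0.95)
  expect_lt(gev_of(cfg_lo), 0.4)
})

test_that("cohorts respect the one-recording-per-age-group design", {
  spec <- cohort_spec(n_subjects = 6, recordings_per_subject = 2:3,
                      epoch_s = 4)
  ch <- generate_cohort(spec, seed = 2)
  dup <- ch |>
    dplyr::count(subject_id, age_group, sleep_state) |>
    dplyr::filter(n > 1)
  expect_identical(nrow(dup), 0L)
  expect_true(all(ch$pma_weeks >= ch$ga_weeks))
  expect_identical(as.character(ch$age_group),
                   as.character(age_group_of(ch$pma_weeks)))
  expect_true(all(vapply(ch$epoch, inherits, logical(1), "eeg_epoch")))
  expect_error(cohort_spec(recordings_per_subject = 5), "age group")
  # determinism of the full cohort
  ch2 <- generate_cohort(spec, seed = 2)
  expect_identical(ch$epoch[[1]]$data, ch2$epoch[[1]]$data)
})

test_that("ground-truth duration is exactly linear in PMA without intercepts", {
  spec <- cohort_spec(n_subjects = 8, recordings_per_subject = 2,
                      duration_subject_sd = 0, epoch_s = 4,
                      duration_range_ms = c(1, 1000))
  ch <- generate_cohort(spec, seed = 3)
  qs <- ch[ch$sleep_state == "QS", ]
  expect_equal(cor(qs$gt_duration_ms, qs$pma_weeks), -1, tolerance = 1e-12)
})

test_that("age grouping uses the published boundaries", {
  pma <- c(26, 31.9, 32, 33.9, 34, 36.9, 37, 44)
  expect_identical(as.character(age_group_of(pma)),
                   c("le31", "le31", "g32_33", "g32_33",
                     "g34_36", "g34_36", "ge37", "ge37"))
})
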