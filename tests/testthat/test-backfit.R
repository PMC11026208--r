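# Backfitting, smoothing, run segmentation and microstate metrics.

test_that("label assignment matches exact maps regardless of sign and scale", {
  maps <- generate_maps(3, 8, seed = 2)
  idx <- c(1, 2, 3, 2, 1)
  sgn <- c(1, -1, 1, -1, -1)
  ep <- eeg_epoch(t(maps$maps[idx, ] * sgn * 2), 100,
                  reference = "common_average")
  lab <- assign_labels(ep, maps)
  expect_identical(lab$labels, as.integer(idx))
  expect_true(all(lab$corr > 1 - 1e-9))
  ep5 <- eeg_epoch(ep$data * 5, 100, reference = "common_average")
  expect_identical(assign_labels(ep5, maps)$labels, lab$labels)
})

test_that("zero-variance samples inherit the previous label and are flagged", {
  maps <- generate_maps(2, 6, seed = 3)
  V <- t(maps$maps[c(2, 2, 1), ])
  V[, 2] <- 0
  ep <- eeg_epoch(V, 100, reference = "common_average")
  lab <- assign_labels(ep, maps)
  expect_identical(lab$labels, c(2L, 2L, 1L))
  expect_identical(lab$flagged, c(FALSE, TRUE, FALSE))
  # a flat FIRST sample falls back to map 1
  V2 <- t(maps$maps[c(1, 2), ]); V2[, 1] <- 0
  lab2 <- assign_labels(eeg_epoch(V2, 100, reference = "common_average"), maps)
  expect_identical(lab2$labels[1], 1L)
})

test_that("smoothing with zero penalty is the identity on labels", {
  fx <- make_default_epoch(seed = 4, epoch_s = 10)
  lab <- assign_labels(fx$epoch, fx$maps)
  out <- smooth_labels(fx$epoch, fx$maps, lab, penalty = 0)
  expect_identical(out$labels, lab$labels)
})

test_that("smoothing removes injected single-sample flips in clean data", {
  fx <- make_default_epoch(seed = 5, epoch_s = 20, snr = Inf)
  lab <- assign_labels(fx$epoch, fx$maps)
  sm_clean <- smooth_labels(fx$epoch, fx$maps, lab)
  corrupted <- lab$labels
  set.seed(99)
  pos <- sample(100:1900, 25)
  corrupted[pos] <- ((corrupted[pos] + 1L) %% 4L) + 1L
  bad <- ms_labels(corrupted, lab$fs, lab$k)
  sm <- smooth_labels(fx$epoch, fx$maps, bad)
  # the corruptions vanish: smoothing the corrupted sequence lands (almost)
  # exactly where smoothing the clean sequence does
  expect_gt(mean(sm$labels == sm_clean$labels), 0.995)
})

test_that("smoothing lengthens mean run length on noisy epochs", {
  for (seed in c(6, 7, 8)) {
    fx <- make_default_epoch(seed = seed, epoch_s = 15)
    lab <- assign_labels(fx$epoch, fx$maps)
    sm <- smooth_labels(fx$epoch, fx$maps, lab)
    expect_gte(mean(segment_runs(sm)$length),
               mean(segment_runs(lab)$length))
  }
})

test_that("run segmentation encodes and round-trips exactly", {
  lab <- ms_labels(c(1, 1, 2, 2, 2, 1), 100, 2)
  runs <- segment_runs(lab)
  expect_equal(runs$label, c(1L, 2L, 1L))
  expect_equal(runs$length, c(2L, 3L, 1L))
  expect_equal(runs$start, c(1L, 3L, 6L))
  expect_identical(rep.int(runs$label, runs$length), lab$labels)
  const <- segment_runs(ms_labels(rep(3L, 50), 100, 3))
  expect_identical(nrow(const), 1L)
  expect_identical(const$length, 50L)
  set.seed(12)
  rnd <- ms_labels(sample(1:4, 500, replace = TRUE), 100, 4)
  rr <- segment_runs(rnd)
  expect_identical(rep.int(rr$label, rr$length), rnd$labels)
  expect_true(all(diff(rr$label) != 0L))
})

test_that("metrics match closed forms and satisfy the coverage identities", {
  runs <- segment_runs(ms_labels(rep(c(1L, 2L), each = 50), 100, 2))
  m <- ms_metrics(runs)
  expect_equal(m$per_map$duration_s, c(0.5, 0.5))
  expect_equal(m$per_map$occurrence_hz, c(1, 1))
  expect_equal(m$per_map$coverage, c(0.5, 0.5))
  expect_equal(m$mean_duration_s * m$mean_occurrence_hz, 1)

  set.seed(21)
  rnd <- ms_labels(sample(1:4, 2000, replace = TRUE,
                          prob = c(0.4, 0.3, 0.2, 0.1)), 100, 4)
  m2 <- ms_metrics(segment_runs(rnd))
  expect_equal(sum(m2$per_map$coverage), 1, tolerance = 1e-12)
  expect_equal(m2$per_map$coverage,
               m2$per_map$occurrence_hz * m2$per_map$duration_s,
               tolerance = 1e-9)
  # a map with no runs gets zeros and a flag
  sparse <- ms_metrics(segment_runs(ms_labels(c(1, 1, 2), 100, 3)))
  expect_true(sparse$per_map$absent[3])
  expect_equal(sparse$per_map$coverage[3], 0)
})

test_that("backfitting a noiseless epoch recovers the generating sequence", {
  fx <- make_default_epoch(seed = 9, epoch_s = 30, snr = Inf,
                           preprocess = FALSE)
  ep <- rereference_common_average(fx$raw)
  lab <- assign_labels(ep, fx$maps)
  pk <- gfp_peaks(global_field_power(ep))
  agree <- mean(lab$labels[pk] == fx$labels$labels[pk])
  expect_gte(agree, 0.99)
})

test_that("recovered mean duration tracks the generating duration", {
  # at the calibrated snr the absolute duration is compressed (noise splits
  # long runs more often than short ones) but the ordering is preserved,
  # which is what the maturation analysis relies on
  durs <- c(150, 250)
  est <- vapply(seq_along(durs), function(i) {
    fx <- make_default_epoch(seed = 40 + i, epoch_s = 60,
                             mean_duration_ms = durs[i])
    pk <- gfp_peaks(global_field_power(fx$epoch))
    fit <- modified_kmeans(t(fx$epoch$data[, pk]), 4, n_restarts = 10,
                           seed = i)
    backfit_epoch(fx$epoch, fit$mapset)$metrics$mean_duration_s
  }, numeric(1))
  expect_lt(abs(est[1] * 1000 - durs[1]) / durs[1], 0.5)
  expect_lt(abs(est[2] * 1000 - durs[2]) / durs[2], 0.5)
  expect_lt(est[1], est[2])
})
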