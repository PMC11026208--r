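# GFP, peaks, spatial correlation, modified k-means, GEV, map matching.

test_that("GFP matches its closed forms and is homogeneous", {
  ep <- eeg_epoch(rbind(c(1, 2, 0), c(-1, -2, 0)), 100,
                  reference = "common_average")
  expect_equal(global_field_power(ep), c(1, 2, 0))
  ep3 <- eeg_epoch(matrix(5, 4, 3), 100)  # spatially constant
  ep3$reference <- "common_average"
  expect_equal(global_field_power(ep3), c(0, 0, 0))
  set.seed(1)
  ep4 <- rereference_common_average(eeg_epoch(matrix(rnorm(12), 4, 3), 100))
  expect_equal(global_field_power(eeg_epoch(3 * ep4$data, 100,
                                            reference = "common_average")),
               3 * global_field_power(ep4))
  expect_error(global_field_power(eeg_epoch(matrix(1:12, 4, 3), 100)),
               "average-referenced")
})

test_that("GFP peaks are strict interior maxima with plateau-onset rule", {
  expect_identical(gfp_peaks(c(0, 1, 0, 2, 0)), c(2L, 4L))
  expect_identical(gfp_peaks(1:10), integer(0))
  expect_identical(gfp_peaks(c(0, 1, 1, 0)), 2L)
  # brute-force plateau scan oracle on random step series
  set.seed(42)
  x <- sample(0:3, 50, replace = TRUE)
  naive <- integer(0)
  for (i in 2:49) {
    if (x[i - 1] < x[i] && x[i] >= x[i + 1]) naive <- c(naive, i)
  }
  expect_identical(gfp_peaks(x), naive)
})

test_that("spatial correlation honours identity, polarity and orthogonality", {
  a <- c(1, -1, 2, -2); b <- c(1, 1, -1, -1)
  expect_equal(spatial_correlation(a, a), 1)
  expect_equal(spatial_correlation(a, -a, polarity_invariant = TRUE), 1)
  expect_equal(spatial_correlation(a, -a, polarity_invariant = FALSE), -1)
  expect_equal(spatial_correlation(c(1, -1, 0, 0), c(0, 0, 1, -1)), 0)
  expect_error(spatial_correlation(a, rep(2, 4)), "zero-variance")
})

test_that("modified k-means recovers noiseless generators exactly", {
  maps <- generate_maps(2, 6, seed = 3)
  set.seed(5)
  signs <- sample(c(-1, 1), 40, replace = TRUE)
  X <- maps$maps[rep(1:2, each = 20), ] * signs
  fit <- modified_kmeans(X, 2, seed = 9)
  expect_true(all(map_recovery_corr(fit$mapset, maps) > 1 - 1e-6))
  expect_equal(fit$gev, 1, tolerance = 1e-9)
})

test_that("saturated model (k = n samples) explains everything", {
  set.seed(8)
  X <- matrix(rnorm(5 * 7), 5, 7)
  fit <- modified_kmeans(X, 5, n_restarts = 5, seed = 2)
  expect_equal(fit$gev, 1, tolerance = 1e-9)
  expect_error(modified_kmeans(X, 6, seed = 1), "fewer samples")
})

test_that("clustering is polarity- and scale-invariant", {
  fx <- make_default_epoch(seed = 2, epoch_s = 20)
  pk <- gfp_peaks(global_field_power(fx$epoch))
  X <- t(fx$epoch$data[, pk])
  set.seed(31)
  flip <- sample(c(-1, 1), nrow(X), replace = TRUE)
  f1 <- modified_kmeans(X, 4, n_restarts = 5, seed = 7)
  f2 <- modified_kmeans(X * flip, 4, n_restarts = 5, seed = 7)
  f3 <- modified_kmeans(X * 5, 4, n_restarts = 5, seed = 7)
  expect_equal(f1$gev, f2$gev, tolerance = 1e-9)
  expect_identical(f1$peak_labels, f2$peak_labels)
  C <- abs(tcrossprod(f1$mapset$maps, f2$mapset$maps))
  expect_true(all(diag(C) > 1 - 1e-9))
  expect_identical(f1$peak_labels, f3$peak_labels)
  expect_equal(f1$gev, f3$gev, tolerance = 1e-9)
})

test_that("k-means explained variance matches the exhaustive-search oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(8 * 4), 8, 4)
    for (k in 2:3) {
      fit <- modified_kmeans(X, k, n_restarts = 50, seed = seed)
      expect_equal(fit$gev, oracle_best_ev(X, k), tolerance = 1e-9)
    }
  }
})

test_that("GEV hits its closed-form extremes", {
  maps <- generate_maps(2, 6, seed = 4)
  ep <- eeg_epoch(t(maps$maps[c(1, 2, 1), ] * c(2, -3, 1)), 100,
                  reference = "common_average")
  expect_equal(compute_gev(ep, maps, c(1, 2, 1)), 1, tolerance = 1e-12)
  # orthogonal complement map set: zero explained variance
  M <- matrix(0, 2, 6)
  M[1, ] <- c(1, -1, 0, 0, 0, 0); M[2, ] <- c(0, 0, 1, -1, 0, 0)
  basis <- ms_mapset(M)
  V <- cbind(c(0, 0, 0, 0, 1, -1)) %*% rbind(c(1, 2, 3))
  ep2 <- eeg_epoch(V, 100, reference = "common_average")
  expect_equal(compute_gev(ep2, basis, c(1, 1, 2)), 0, tolerance = 1e-12)
  expect_error(compute_gev(eeg_epoch(matrix(0, 6, 3), 100,
                                     reference = "common_average"),
                           maps, c(1, 1, 1)), "all-zero")
})

test_that("group maps reproduce identical inputs and ignore pooling order", {
  maps <- generate_maps(4, 9, seed = 6)
  sets <- replicate(5, maps, simplify = FALSE)
  g <- group_maps(sets, 4, seed = 3)
  expect_true(all(map_recovery_corr(g, maps) > 1 - 1e-9))
  # permutation invariance of the pooled input
  pert <- lapply(1:6, function(i) {
    set.seed(i)
    ms_mapset(maps$maps + matrix(rnorm(36, sd = 0.02), 4, 9))
  })
  g1 <- group_maps(pert, 4, seed = 5)
  g2 <- group_maps(rev(pert), 4, seed = 5)
  C <- abs(tcrossprod(g1$maps, g2$maps))
  expect_true(all(apply(C, 1, max) > 1 - 1e-6))
})

test_that("map matching undoes shifts and sign flips and equals brute force", {
  ref <- generate_maps(4, 9, seed = 10)
  shifted <- ms_mapset(ref$maps[c(2, 3, 4, 1), ])
  m <- match_map_order(ref, list(shifted))
  expect_true(all(abs(diag(tcrossprod(ref$maps, m$mapsets[[1]]$maps))) >
                    1 - 1e-9))
  flipped <- ms_mapset(ref$maps * c(-1, 1, -1, 1))
  m2 <- match_map_order(ref, list(flipped))
  expect_identical(m2$permutations[[1]], 1:4)
  # brute-force oracle on unrelated sets
  for (seed in 1:3) {
    other <- generate_maps(4, 9, seed = 20 + seed)
    got <- match_map_order(ref, list(other))
    C <- abs(tcrossprod(ref$maps, other$maps))
    perms <- rbind(expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4))
    best <- -Inf; best_p <- NULL
    for (r in seq_len(nrow(perms))) {
      p <- as.integer(perms[r, ])
      if (length(unique(p)) < 4) next
      sc <- mean(C[cbind(1:4, p)])
      if (sc > best + 1e-12) { best <- sc; best_p <- p }
    }
    expect_equal(mean(C[cbind(1:4, got$permutations[[1]])]), best,
                 tolerance = 1e-12)
  }
})
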