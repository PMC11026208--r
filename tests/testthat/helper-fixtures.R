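# Fixtures are generated in code; nothing is read from disk.

# a short synthetic epoch with known ground truth, preprocessed and ready
# for clustering/backfitting
make_default_epoch <- function(seed = 1L, epoch_s = 60, snr = default_snr(),
                               mean_duration_ms = 200, preprocess = TRUE) {
  cfg <- ground_truth_config(mean_duration_ms = mean_duration_ms, snr = snr,
                             epoch_s = epoch_s)
  maps <- generate_maps(4, 9, seed = seed)
  lab <- sample_label_sequence(cfg, round(cfg$fs * epoch_s), seed = seed + 100L)
  ep <- synthesize_epoch(maps, lab, cfg, seed = seed + 200L)
  list(epoch = if (preprocess) preprocess_epoch(ep) else ep,
       raw = ep, maps = maps, labels = lab, config = cfg)
}

# exhaustive-search oracle for the polarity-invariant clustering objective:
# maximal explained variance over ALL assignments of n samples to k maps,
# where each cluster's optimal map is the leading eigenvector of its scatter
oracle_best_ev <- function(X, k) {
  X <- X - rowMeans(X)
  n <- nrow(X)
  tot <- sum(X^2)
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  best <- -Inf
  for (g in seq_len(nrow(grid))) {
    lab <- as.integer(grid[g, ])
    if (length(unique(lab)) < k) next
    ev <- 0
    for (j in seq_len(k)) {
      S <- crossprod(X[lab == j, , drop = FALSE])
      ev <- ev + max(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    }
    best <- max(best, ev / tot)
  }
  best
}

# independent Benjamini-Hochberg oracle straight from the step-up definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

map_recovery_corr <- function(found, truth) {
  C <- abs(tcrossprod(found$maps, truth$maps))
  apply(C, 2, max)
}
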