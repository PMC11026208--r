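# Group-level topography comparison (TANOVA), Hurst exponents of microstate
# sequences via detrended fluctuation analysis, and metric-vs-age
# associations.

#' Topographic permutation test of map similarity (TANOVA)
#'
#' Compares two scalp maps using the polarity-invariant spatial correlation
#' as effect size. The null distribution is built by randomly permuting the
#' channel order of the second map `n_perm` times and recomputing the effect
#' size; the add-one estimator gives the p-value. A significant result means
#' the maps are SIMILAR (spatially correlated beyond chance), not different.
#'
#' @param map_a,map_b Numeric topography vectors over the same channels.
#' @param n_perm Number of channel permutations (default 5000).
#' @param seed Integer seed.
#' @return A list of class `ms_tanova`: `effect_size`, `p`, `n_perm`,
#'   `null_mean`, `null_sd`.
#' @export
tanova_similarity <- function(map_a, map_b, n_perm = 5000L, seed = 1L) {
  stopifnot(length(map_a) == length(map_b), n_perm >= 100L)
  a <- map_a - mean(map_a)
  b <- map_b - mean(map_b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("constant map has no topography", call. = FALSE)
  a <- a / na; b <- b / nb
  obs <- abs(sum(a * b))
  nch <- length(a)
  null <- numeric(n_perm)
  with_local_seed(seed, {
    idx <- matrix(0L, n_perm, nch)
    for (i in seq_len(n_perm)) idx[i, ] <- sample.int(nch)
    B <- matrix(b[idx], n_perm, nch)
    null <- abs(B %*% a)[, 1L]
  })
  res <- list(effect_size = obs,
              p = (1 + sum(null >= obs)) / (1 + n_perm),
              n_perm = as.integer(n_perm),
              null_mean = mean(null), null_sd = stats::sd(null))
  class(res) <- "ms_tanova"
  res
}

#' @export
print.ms_tanova <- function(x, ...) {
  cat(sprintf("<ms_tanova> |r| = %.3f, p = %.4g (%d channel permutations)\n",
              x$effect_size, x$p, x$n_perm))
  invisible(x)
}

#' @rdname tanova_similarity
#' @param x A `ms_tanova` object.
#' @param ... Unused.
#' @export
glance.ms_tanova <- function(x, ...) {
  tibble::tibble(effect_size = x$effect_size, p = x$p, n_perm = x$n_perm,
                 null_mean = x$null_mean, null_sd = x$null_sd)
}

# --- DFA / Hurst ------------------------------------------------------------

# order-1 detrended fluctuation function over log-spaced box sizes
dfa_fluctuation <- function(x, n_sizes = 15L, min_size = 10L) {
  n <- length(x)
  y <- cumsum(x - mean(x))
  max_size <- floor(n / 4)
  if (max_size <= min_size) stop("sequence too short for DFA", call. = FALSE)
  sizes <- unique(round(exp(seq(log(min_size), log(max_size),
                                length.out = n_sizes))))
  Fn <- vapply(sizes, function(s) {
    nb <- n %/% s
    Y <- matrix(y[seq_len(nb * s)], nrow = s)
    tc <- seq_len(s) - (s + 1) / 2
    beta <- colSums(Y * tc) / sum(tc^2)
    res <- Y - outer(tc, beta) - matrix(colMeans(Y), s, nb, byrow = TRUE)
    sqrt(mean(res^2))
  }, numeric(1))
  list(sizes = sizes, Fn = Fn)
}

dfa_slope <- function(x, ...) {
  f <- dfa_fluctuation(x, ...)
  ok <- f$Fn > 0
  if (sum(ok) < 3L) return(NA_real_)
  lf <- log(f$Fn[ok]); ls <- log(f$sizes[ok])
  sum((ls - mean(ls)) * (lf - mean(lf))) / sum((ls - mean(ls))^2)
}

#' Hurst exponent of a microstate label sequence
#'
#' Estimates long-range temporal dependence of the categorical microstate
#' sequence. Each of the `2^(k-1) - 1` nontrivial bipartitions of the k
#' labels maps the sequence to a +/-1 series; its cumulative sum forms a
#' random walk whose order-1 detrended fluctuation function F(n) is fitted
#' on log-log axes over ~15 log-spaced box sizes in `[10, length/4]`. H is
#' the mean slope over bipartitions; 0.5 is the memoryless value, larger
#' values indicate persistence. The estimate is invariant under relabelling
#' of the maps because the bipartition set is label-symmetric.
#'
#' @param labels A [ms_labels()] object or integer vector (length >= 1000).
#' @param k Number of maps (defaults to the value stored on `labels`).
#' @return The Hurst exponent estimate (scalar).
#' @export
hurst_dfa <- function(labels, k = NULL) {
  if (inherits(labels, "ms_labels")) {
    lab <- labels$labels
    k <- k %||% labels$k
  } else {
    lab <- as.integer(labels)
    k <- k %||% max(lab)
  }
  if (length(lab) < 1000L) stop("need >= 1000 samples for DFA", call. = FALSE)
  if (length(unique(lab)) < 2L) {
    warning("constant label sequence: Hurst exponent undefined")
    return(NA_real_)
  }
  n_bip <- 2^(k - 1L) - 1L
  slopes <- vapply(0:(n_bip - 1L), function(mask) {
    inset <- c(TRUE, bitwAnd(mask, 2^(0:(k - 2L))) > 0)
    x <- ifelse(inset[lab], 1, -1)
    if (stats::sd(x) == 0) return(NA_real_)
    dfa_slope(x)
  }, numeric(1))
  mean(slopes, na.rm = TRUE)
}

# --- metric vs age associations --------------------------------------------

#' Associations between per-epoch microstate metrics and post-menstrual age
#'
#' For each sleep state and each metric column, computes the Pearson
#' correlation with PMA, its two-sided p-value, and the least-squares slope
#' (metric units per week). The input is the tidy per-epoch table produced
#' by [run_individual_analysis()] (or any table with `pma_weeks`,
#' `sleep_state` and metric columns); the same table, pivoted long, is the
#' export a mixed-effects model would consume.
#'
#' @param table A data frame with columns `pma_weeks`, `sleep_state` and the
#'   metric columns.
#' @param metrics Character vector of metric column names (default
#'   `mean_duration_s`, `mean_occurrence_hz`, `hurst`).
#' @return A tibble with one row per (sleep_state, metric): `r`, `p`, `n`,
#'   `slope`.
#' @export
metric_age_association <- function(table,
                                   metrics = c("mean_duration_s",
                                               "mean_occurrence_hz",
                                               "hurst")) {
  metrics <- intersect(metrics, names(table))
  if (length(metrics) == 0L) stop("no metric columns found", call. = FALSE)
  long <- tidyr::pivot_longer(table, dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  long |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::group_by(.data$sleep_state, .data$metric) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3L) stop("need >= 3 epochs per sleep state", call. = FALSE)
      if (stats::sd(d$value) == 0 || stats::sd(d$pma_weeks) == 0) {
        stop("constant metric or constant PMA", call. = FALSE)
      }
      ct <- stats::cor.test(d$value, d$pma_weeks)
      slope <- stats::cov(d$value, d$pma_weeks) / stats::var(d$pma_weeks)
      tibble::tibble(r = unname(ct$estimate), p = ct$p.value,
                     n = nrow(d), slope = slope)
    }) |>
    dplyr::ungroup()
}

#' Long-format export of per-epoch metrics for external model fitting
#'
#' Pivots the per-epoch metric table into the tidy long format (one row per
#' epoch x metric) that a mixed-effects model with subject random intercepts
#' consumes.
#'
#' @inheritParams metric_age_association
#' @return A long tibble: subject_id, ga_weeks, pma_weeks, sleep_state,
#'   metric, value.
#' @export
metrics_long_table <- function(table,
                               metrics = c("mean_duration_s",
                                           "mean_occurrence_hz",
                                           "hurst")) {
  metrics <- intersect(metrics, names(table))
  keep <- intersect(c("subject_id", "ga_weeks", "pma_weeks", "sleep_state"),
                    names(table))
  tidyr::pivot_longer(dplyr::select(table, dplyr::all_of(c(keep, metrics))),
                      dplyr::all_of(metrics),
                      names_to = "metric", values_to = "value")
}
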