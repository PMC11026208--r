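# Microstate identification: GFP, GFP peaks, polarity-invariant modified
# k-means, Krzanowski-Lai model selection, GEV, group-level pooling and map
# matching.

#' Microstate map sets
#'
#' A `ms_mapset` is a k x channels matrix of scalp topographies, each
#' zero-mean across channels and of unit L2 norm. Maps are defined only up
#' to sign; every comparison in the package is polarity-invariant, and the
#' stored sign merely fixes the channel with the largest absolute loading to
#' be positive for display.
#'
#' @param maps Numeric matrix, k x channels.
#' @param channel_names Optional channel labels.
#' @return An object of class `ms_mapset`.
#' @export
ms_mapset <- function(maps, channel_names = NULL) {
  maps <- as.matrix(maps)
  maps <- fix_map_signs(normalize_rows(maps))
  if (is.null(channel_names)) {
    channel_names <- if (ncol(maps) == 9L) neonatal_montage() else
      paste0("ch", seq_len(ncol(maps)))
  }
  colnames(maps) <- channel_names
  rownames(maps) <- paste0("M", seq_len(nrow(maps)))
  structure(list(maps = maps, k = nrow(maps), channel_names = channel_names),
            class = "ms_mapset")
}

#' @export
print.ms_mapset <- function(x, ...) {
  cat(sprintf("<ms_mapset> %d maps x %d channels\n", x$k, ncol(x$maps)))
  print(round(x$maps, 3))
  invisible(x)
}

#' Global field power
#'
#' GFP(t) is the population standard deviation of the voltage vector across
#' channels at sample t. Peaks of GFP mark moments of high topographic
#' signal-to-noise and are the samples used for clustering.
#'
#' @param epoch An average-referenced [eeg_epoch()].
#' @return Numeric vector of per-sample GFP values.
#' @export
global_field_power <- function(epoch) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  if (!is_average_referenced(epoch)) {
    stop("epoch must be average-referenced before computing GFP", call. = FALSE)
  }
  x <- center_samples(epoch$data)
  sqrt(colSums(x^2) / nrow(x))
}

#' Locate GFP peaks
#'
#' Strict local maxima: `gfp[i-1] < gfp[i] >= gfp[i+1]`, so a plateau is
#' credited to its onset sample; endpoints are never peaks.
#'
#' @param gfp Numeric series (length >= 3).
#' @return Integer vector of 1-based peak indices.
#' @export
gfp_peaks <- function(gfp) {
  n <- length(gfp)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[gfp[i - 1L] < gfp[i] & gfp[i] >= gfp[i + 1L]]
}

#' Spatial correlation between two topographies
#'
#' Pearson correlation across channels of the two average-referenced maps;
#' with `polarity_invariant = TRUE` (the package-wide convention) the
#' absolute value is returned.
#'
#' @param a,b Numeric vectors over the same channels (length >= 2).
#' @param polarity_invariant Return `|r|` instead of signed r.
#' @return A scalar in `[-1, 1]` (or `[0, 1]` when invariant).
#' @export
spatial_correlation <- function(a, b, polarity_invariant = TRUE) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  a <- a - mean(a); b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("zero-variance topography has no spatial correlation", call. = FALSE)
  }
  r <- sum(a * b) / (na * nb)
  if (polarity_invariant) abs(r) else r
}

# --- modified k-means -------------------------------------------------------

#' Polarity-invariant modified k-means clustering of topographies
#'
#' Alternates (i) assigning each sample topography to the map with maximal
#' squared spatial correlation (polarity ignored) and (ii) re-estimating each
#' map as the first principal eigenvector of the outer-product sum of its
#' assigned samples. Convergence is declared when the relative change in
#' explained variance falls below `tol`; the best of `n_restarts` random
#' initialisations (by explained variance) is returned. An empty cluster is
#' reseeded from the currently worst-fit sample.
#'
#' @param samples Numeric matrix, n x channels, of average-referenced
#'   topographies (typically the epoch at its GFP peaks, samples in rows).
#' @param k Number of maps (`2 <= k <= n`).
#' @param n_restarts Random restarts (default 20).
#' @param max_iter Iteration cap per restart (default 500).
#' @param tol Relative explained-variance convergence tolerance.
#' @param seed Integer seed; the fit is a pure function of it.
#' @return An object of class `ms_kmeans`: `mapset`, `peak_labels`, `gev`
#'   (explained variance on the input samples), `dispersion` (the
#'   within-cluster dispersion W(k): the trace of the within-cluster scatter
#'   under polarity-invariant projection, i.e. the GFP-weighted variance the
#'   k maps leave unexplained — the quantity the clustering minimises and
#'   the Krzanowski-Lai criterion consumes), `n_iter`, `converged`.
#' @export
modified_kmeans <- function(samples, k, n_restarts = 20L, max_iter = 500L,
                            tol = 1e-6, seed = 1L) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  if (n < k) stop("fewer samples than clusters", call. = FALSE)
  X <- samples - rowMeans(samples)          # average-reference each sample
  norms2 <- rowSums(X^2)
  keep <- norms2 > 0
  tot <- sum(norms2)
  Xn <- normalize_rows(X, allow_zero = TRUE)

  best <- NULL
  with_local_seed(seed, {
    for (r in seq_len(n_restarts)) {
      fit <- mk_once(X, Xn, norms2, keep, tot, k, max_iter, tol)
      if (is.null(best) || fit$gev > best$gev) best <- fit
    }
  })
  maps <- fix_map_signs(best$maps)
  res <- list(
    mapset = ms_mapset(maps),
    peak_labels = best$labels,
    gev = best$gev,
    dispersion = (1 - best$gev) * tot,
    n_iter = best$n_iter,
    converged = best$converged
  )
  class(res) <- "ms_kmeans"
  res
}

# one restart; X raw zero-mean samples, Xn row-normalised
mk_once <- function(X, Xn, norms2, keep, tot, k, max_iter, tol) {
  n <- nrow(X)
  nrm <- sqrt(norms2)
  init <- sample(which(keep), k)
  M <- Xn[init, , drop = FALSE]
  ev_old <- -Inf; converged <- FALSE; it <- 0L
  labels <- rep(1L, n)
  repeat {
    it <- it + 1L
    P <- abs(Xn %*% t(M))                 # n x k |correlations|
    labels <- max.col(P, ties.method = "first")
    pbest <- P[cbind(seq_len(n), labels)]
    ev_num <- (pbest * nrm)^2             # (x . m)^2 on the raw samples
    ev <- sum(ev_num[keep]) / tot
    # reseed empty clusters from the worst-fit sample
    empt <- setdiff(seq_len(k), unique(labels[keep]))
    if (length(empt) > 0) {
      worst <- order(pbest)
      worst <- worst[keep[worst]][seq_along(empt)]
      M[empt, ] <- Xn[worst, , drop = FALSE]
      labels[worst] <- empt
    }
    # update maps: leading eigenvector of each cluster's scatter
    for (j in seq_len(k)) {
      idx <- which(labels == j & keep)
      if (length(idx) == 0L) next
      S <- crossprod(X[idx, , drop = FALSE])
      M[j, ] <- eigen(S, symmetric = TRUE)$vectors[, 1L]
    }
    M <- normalize_rows(M)
    if (is.finite(ev_old) && abs(ev - ev_old) <= tol * max(ev_old, 1e-12)) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    ev_old <- ev
  }
  # final assignment and explained variance with the final maps
  P <- abs(Xn %*% t(M))
  labels <- max.col(P, ties.method = "first")
  ev <- sum((P[cbind(seq_len(n), labels)] * nrm)[keep]^2) / tot
  list(maps = M, labels = labels, gev = ev, n_iter = it, converged = converged)
}

#' @export
print.ms_kmeans <- function(x, ...) {
  cat(sprintf(
    "<ms_kmeans> k=%d, explained variance %.3f, W=%.2f, %s in %d iter\n",
    x$mapset$k, x$gev, x$dispersion,
    if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a microstate clustering fit
#'
#' @param x A `ms_kmeans` object.
#' @param ... Unused.
#' @return A tibble with one row per (map, channel) loading.
#' @export
tidy.ms_kmeans <- function(x, ...) {
  m <- x$mapset$maps
  tibble::tibble(
    map = rep(rownames(m), each = ncol(m)),
    channel = rep(colnames(m), times = nrow(m)),
    loading = as.vector(t(m))
  )
}

#' One-row summary of a microstate clustering fit
#'
#' @param x A `ms_kmeans` object.
#' @param ... Unused.
#' @return A one-row tibble: k, explained variance, dispersion, iterations,
#'   convergence flag.
#' @export
glance.ms_kmeans <- function(x, ...) {
  tibble::tibble(k = x$mapset$k, gev = x$gev, dispersion = x$dispersion,
                 n_iter = x$n_iter, converged = x$converged)
}

#' Global explained variance of a labelled epoch
#'
#' GEV is the GFP-weighted fraction of topographic variance explained by the
#' assigned maps: `sum_t (GFP_t * corr(v_t, map_label(t)))^2 / sum_t GFP_t^2`,
#' with polarity-invariant correlations. For zero-mean unit-norm maps this
#' reduces to `sum_t (v_t . m_label(t))^2 / sum_t ||v_t||^2`.
#'
#' @param epoch An average-referenced [eeg_epoch()].
#' @param mapset A [ms_mapset()].
#' @param labels An integer label per sample (or a `ms_labels` object).
#' @return GEV in `[0, 1]`.
#' @export
compute_gev <- function(epoch, mapset, labels) {
  stopifnot(inherits(epoch, "eeg_epoch"), inherits(mapset, "ms_mapset"))
  lab <- as.integer(labels)
  V <- center_samples(epoch$data)
  tot <- sum(V^2)
  if (tot == 0) stop("all-zero epoch has undefined GEV", call. = FALSE)
  if (length(lab) != ncol(V)) stop("labels must cover all samples", call. = FALSE)
  proj <- t(V) %*% t(mapset$maps)          # samples x k
  sum(proj[cbind(seq_along(lab), lab)]^2) / tot
}

# --- Krzanowski-Lai selection ----------------------------------------------

#' Select the number of microstate maps by the Krzanowski-Lai criterion
#'
#' Runs [modified_kmeans()] for every k in `(k_min-1)..(k_max+1)` (the two
#' boundary fits exist only to give the difference terms at the range ends),
#' computes the within-cluster dispersion W(k), the weighted differences
#' `DIFF(k) = (k-1)^(2/m) W(k-1) - k^(2/m) W(k)` with effective dimension
#' `m = channels - 1` (the common average removes one dimension), and the
#' elbow statistic `KL(k) = |DIFF(k)| / |DIFF(k+1)|`. The selected k is the
#' argmax of KL over `k_min..k_max`, restricted to k with `DIFF(k) > 0`: an
#' elbow is a point where the weighted dispersion still drops, while past
#' the true cluster count DIFF fluctuates around zero and the KL ratio
#' would amplify that noise into spurious maxima at large k. Non-finite KL
#' values are likewise excluded; all exclusions remain visible in the
#' returned curve.
#'
#' @inheritParams modified_kmeans
#' @param k_min,k_max Search range (defaults 3 and 15).
#' @return A list: `k_opt`, `kl` (tibble k, W, diff, kl), and `fits` (the
#'   `ms_kmeans` objects indexed by k as character names).
#' @export
select_k_kl <- function(samples, k_min = 3L, k_max = 15L, n_restarts = 10L,
                        max_iter = 500L, tol = 1e-6, seed = 1L) {
  stopifnot(k_min >= 2L, k_max > k_min + 1L)
  samples <- as.matrix(samples)
  if (nrow(samples) < k_max + 1L) stop("need more samples than k_max", call. = FALSE)
  ks <- (k_min - 1L):(k_max + 1L)
  fits <- lapply(ks, function(k) {
    modified_kmeans(samples, k, n_restarts, max_iter, tol,
                    seed = child_seed(seed, k))
  })
  names(fits) <- ks
  W <- vapply(fits, function(f) f$dispersion, numeric(1))
  m <- ncol(samples) - 1L
  kk <- as.numeric(ks)
  diffs <- c(NA, (kk[-length(kk)])^(2 / m) * W[-length(W)] -
                  (kk[-1])^(2 / m) * W[-1])
  # diffs[i] = DIFF(ks[i]); KL(k) = |DIFF(k)|/|DIFF(k+1)|
  kl <- abs(diffs) / abs(c(diffs[-1], NA))
  curve <- tibble::tibble(k = ks, W = unname(W), diff = unname(diffs),
                          kl = unname(kl))
  sel <- curve$k >= k_min & curve$k <= k_max & is.finite(curve$kl) &
    !is.na(curve$diff) & curve$diff > 0
  if (!any(sel)) {   # degenerate curve: fall back to the unrestricted argmax
    sel <- curve$k >= k_min & curve$k <= k_max & is.finite(curve$kl)
  }
  if (!any(sel)) stop("KL criterion undefined over the whole range", call. = FALSE)
  k_opt <- curve$k[sel][which.max(curve$kl[sel])]
  list(k_opt = as.integer(k_opt), kl = curve, fits = fits)
}

# --- group-level maps and ordering -----------------------------------------

#' Group-level microstate maps from pooled individual maps
#'
#' Pools the maps of all individual map sets in a group and clusters the
#' pooled topographies with the same modified k-means, yielding the group's
#' dominant maps.
#'
#' @param individual_mapsets List of [ms_mapset()] objects sharing a channel
#'   count.
#' @param k Number of group-level maps.
#' @inheritParams modified_kmeans
#' @return A [ms_mapset()] of k maps.
#' @export
group_maps <- function(individual_mapsets, k, n_restarts = 20L, seed = 1L) {
  stopifnot(length(individual_mapsets) > 0)
  nc <- vapply(individual_mapsets, function(m) ncol(m$maps), integer(1))
  if (length(unique(nc)) != 1L) stop("channel counts differ", call. = FALSE)
  pooled <- do.call(rbind, lapply(individual_mapsets, function(m) m$maps))
  if (nrow(pooled) < k) stop("fewer pooled maps than k", call. = FALSE)
  fit <- modified_kmeans(pooled, k, n_restarts = n_restarts, seed = seed)
  fit$mapset
}

#' Match map order across map sets
#'
#' Finds, for every non-reference map set, the label permutation maximizing
#' the mean polarity-invariant spatial correlation with the reference maps,
#' by exhaustive search over the k! permutations (k <= 8). Ties break to the
#' lexicographically smallest permutation.
#'
#' @param reference A [ms_mapset()].
#' @param others A list of [ms_mapset()] objects with the same k and channel
#'   count.
#' @return A list with `mapsets` (reordered copies of `others`),
#'   `permutations` (list of integer vectors; entry j of a permutation gives
#'   the index in the original set that becomes map j) and `mean_corr`.
#' @export
match_map_order <- function(reference, others) {
  stopifnot(inherits(reference, "ms_mapset"))
  k <- reference$k
  if (k > 8L) stop("exhaustive matching supports k <= 8", call. = FALSE)
  perms <- permutations_of(k)
  R <- reference$maps
  out_sets <- vector("list", length(others))
  out_perm <- vector("list", length(others))
  out_corr <- numeric(length(others))
  for (i in seq_along(others)) {
    m <- others[[i]]
    if (!inherits(m, "ms_mapset") || m$k != k) stop("mismatched k", call. = FALSE)
    C <- abs(tcrossprod(R, m$maps))        # k x k |corr| (unit-norm rows)
    scores <- vapply(seq_len(nrow(perms)), function(p) {
      mean(C[cbind(seq_len(k), perms[p, ])])
    }, numeric(1))
    best <- which.max(scores)              # which.max takes first = lexicographic
    pp <- perms[best, ]
    out_sets[[i]] <- ms_mapset(m$maps[pp, , drop = FALSE], m$channel_names)
    out_perm[[i]] <- pp
    out_corr[i] <- scores[best]
  }
  list(mapsets = out_sets, permutations = out_perm, mean_corr = out_corr)
}

# all permutations of 1..k in lexicographic order
permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  out <- matrix(0L, 0, k)
  for (first in seq_len(k)) {
    rest <- setdiff(seq_len(k), first)
    out <- rbind(out, cbind(first, matrix(rest[sub], nrow(sub), k - 1L)))
  }
  unname(out)
}
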