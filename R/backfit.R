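# Backfitting: per-sample labelling of a continuous epoch with a map set,
# temporal smoothing, run segmentation and microstate metrics.

#' Microstate label sequences
#'
#' A `ms_labels` object holds a per-sample map assignment for one epoch
#' together with the per-sample polarity-invariant assignment correlation,
#' the sampling rate and the number of maps.
#'
#' @param labels Integer vector of map indices in `1..k`.
#' @param fs Sampling rate in Hz.
#' @param k Number of maps.
#' @param corr Optional numeric vector of assignment correlations.
#' @param flagged Optional logical vector marking degenerate samples
#'   (zero-variance topographies that inherited a neighbour's label).
#' @return An object of class `ms_labels`.
#' @export
ms_labels <- function(labels, fs, k, corr = NULL, flagged = NULL) {
  labels <- unname(as.integer(labels))
  if (any(labels < 1L | labels > k)) stop("labels outside 1..k", call. = FALSE)
  structure(list(labels = labels, fs = as.numeric(fs), k = as.integer(k),
                 corr = if (is.null(corr)) NULL else unname(corr),
                 flagged = if (is.null(flagged)) NULL else unname(flagged)),
            class = "ms_labels")
}

#' @export
as.integer.ms_labels <- function(x, ...) x$labels

#' @export
length.ms_labels <- function(x) length(x$labels)

#' @export
print.ms_labels <- function(x, ...) {
  cat(sprintf("<ms_labels> %d samples @ %g Hz, k=%d, %d runs\n",
              length(x$labels), x$fs, x$k, n_label_runs(x$labels)))
  invisible(x)
}

n_label_runs <- function(lab) sum(diff(lab) != 0L) + 1L

#' Assign every sample of an epoch to its best-matching map
#'
#' Backfits a map set onto the entire continuous epoch: each sample gets the
#' map with maximal polarity-invariant spatial correlation, ties broken by
#' the lowest map index. A zero-variance sample (flat topography) inherits
#' the previous sample's label (map 1 at the first sample) and is flagged.
#'
#' @param epoch An average-referenced [eeg_epoch()].
#' @param mapset A [ms_mapset()] with matching channel count.
#' @return A [ms_labels()] object.
#' @export
assign_labels <- function(epoch, mapset) {
  stopifnot(inherits(epoch, "eeg_epoch"), inherits(mapset, "ms_mapset"))
  if (!is_average_referenced(epoch)) {
    stop("epoch must be average-referenced", call. = FALSE)
  }
  V <- center_samples(epoch$data)
  if (ncol(mapset$maps) != nrow(V)) stop("channel counts differ", call. = FALSE)
  nrm <- sqrt(colSums(V^2))
  A <- abs(t(mapset$maps %*% V))                  # samples x k, |v.m|
  lab <- max.col(A, ties.method = "first")
  corr <- A[cbind(seq_len(nrow(A)), lab)] / ifelse(nrm == 0, NA, nrm)
  flat <- nrm == 0
  if (any(flat)) {
    idx <- which(flat)
    for (i in idx) lab[i] <- if (i == 1L) 1L else lab[i - 1L]
  }
  ms_labels(lab, epoch$fs, mapset$k, corr = corr, flagged = flat)
}

#' Temporally smooth a microstate label sequence
#'
#' Iterative segmentation smoothing: each sample's misfit (residual
#' topographic variance under a candidate map, normalised by the running
#' residual scale) is discounted by `penalty` times the number of
#' same-labelled neighbours within `+/-window` samples, and labels are
#' re-assigned to the minimiser until a fixed point (or 100 iterations).
#' The window is one-sided: `window = round(window_ms * fs / 1000)` samples
#' on each side (3 samples at the default 30 ms, 100 Hz). A penalty of 0
#' returns the input labels unchanged.
#'
#' @param epoch The average-referenced [eeg_epoch()] the labels belong to.
#' @param mapset The [ms_mapset()] used for backfitting.
#' @param labels A [ms_labels()] object (e.g. from [assign_labels()]).
#' @param window_ms Smoothing half-window in milliseconds (default 30).
#' @param penalty Non-smoothness penalty factor (default 1).
#' @return A smoothed [ms_labels()] object.
#' @export
smooth_labels <- function(epoch, mapset, labels, window_ms = 30, penalty = 1) {
  stopifnot(inherits(epoch, "eeg_epoch"), inherits(mapset, "ms_mapset"),
            inherits(labels, "ms_labels"), window_ms >= 0, penalty >= 0)
  if (penalty == 0) return(labels)
  V <- center_samples(epoch$data)
  nch <- nrow(V)
  nt <- ncol(V)
  k <- mapset$k
  b <- max(0L, as.integer(round(window_ms * epoch$fs / 1000)))
  v2 <- colSums(V^2)
  proj2 <- t(mapset$maps %*% V)^2                # nt x k, (v.m)^2
  d2 <- v2 - proj2                               # residual variance per map
  lab <- labels$labels
  for (iter in seq_len(100L)) {
    e <- sum(d2[cbind(seq_len(nt), lab)]) / (nt * (nch - 1L))
    if (e <= 0) break
    # neighbour counts per candidate label via cumulative sums
    Nb <- matrix(0, nt, k)
    for (j in seq_len(k)) {
      ind <- as.numeric(lab == j)
      cs <- c(0, cumsum(ind))
      hi <- pmin(nt, seq_len(nt) + b)
      lo <- pmax(0L, seq_len(nt) - b - 1L)
      Nb[, j] <- cs[hi + 1L] - cs[lo + 1L] - ind   # exclude the sample itself
    }
    cost <- d2 / (2 * e * (nch - 1L)) - penalty * Nb
    new_lab <- max.col(-cost, ties.method = "first")
    if (all(new_lab == lab)) break
    lab <- new_lab
  }
  ms_labels(lab, labels$fs, k, corr = labels$corr, flagged = labels$flagged)
}

#' Run-length segmentation of a label sequence
#'
#' Encodes the maximal constant-label runs of a label sequence; expanding the
#' result reproduces the sequence exactly.
#'
#' @param labels A [ms_labels()] object or integer vector.
#' @return A tibble of class `ms_runs` with columns `label`, `start`
#'   (1-based first sample), `length` (samples), plus attributes `fs` and
#'   `k` when available.
#' @export
segment_runs <- function(labels) {
  if (inherits(labels, "ms_labels")) {
    lab <- labels$labels; fs <- labels$fs; k <- labels$k
  } else {
    lab <- as.integer(labels); fs <- NA_real_; k <- max(lab)
  }
  if (length(lab) == 0L) stop("empty label sequence", call. = FALSE)
  r <- rle(lab)
  out <- tibble::tibble(
    label = r$values,
    start = c(1L, head(cumsum(r$lengths), -1L) + 1L),
    length = r$lengths
  )
  attr(out, "fs") <- fs
  attr(out, "k") <- k
  class(out) <- c("ms_runs", class(out))
  out
}

#' Microstate metrics from a run sequence
#'
#' Per-map mean duration (s), occurrence (runs per second) and coverage
#' (fraction of samples), plus the overall mean duration and occurrence over
#' all runs regardless of label. Boundary runs truncated by the epoch edges
#' are included. The identities `coverage_i = occurrence_i * duration_i` and
#' `1 = overall occurrence x overall duration` hold exactly; the occurrence
#' denominator is the full epoch length in seconds (epochs carry no missing
#' data). Maps with no runs get zeros and a flag.
#'
#' @param runs A `ms_runs` tibble from [segment_runs()].
#' @param fs Sampling rate in Hz (defaults to the attribute stored on
#'   `runs`).
#' @param k Number of maps (defaults likewise).
#' @return A list of class `ms_metrics`: `per_map` (tibble map, n_runs,
#'   duration_s, occurrence_hz, coverage, absent), `mean_duration_s`,
#'   `mean_occurrence_hz`, `n_samples`, `fs`.
#' @export
ms_metrics <- function(runs, fs = attr(runs, "fs"), k = attr(runs, "k")) {
  stopifnot(nrow(runs) > 0, is.finite(fs), fs > 0)
  total_samples <- sum(runs$length)
  total_s <- total_samples / fs
  per_map <- runs |>
    dplyr::group_by(label = factor(.data$label, levels = seq_len(k))) |>
    dplyr::summarise(n_runs = dplyr::n(),
                     mean_len = mean(.data$length),
                     tot_len = sum(.data$length), .groups = "drop") |>
    tidyr::complete(label, fill = list(n_runs = 0L, mean_len = 0, tot_len = 0)) |>
    dplyr::mutate(
      map = as.integer(as.character(.data$label)),
      duration_s = .data$mean_len / fs,
      occurrence_hz = .data$n_runs / total_s,
      coverage = .data$tot_len / total_samples,
      absent = .data$n_runs == 0L
    ) |>
    dplyr::select("map", "n_runs", "duration_s", "occurrence_hz",
                  "coverage", "absent") |>
    dplyr::arrange(.data$map)
  out <- list(
    per_map = per_map,
    mean_duration_s = mean(runs$length) / fs,
    mean_occurrence_hz = nrow(runs) / total_s,
    n_samples = total_samples,
    fs = fs
  )
  class(out) <- "ms_metrics"
  out
}

#' @export
print.ms_metrics <- function(x, ...) {
  cat(sprintf("<ms_metrics> mean duration %.3f s, occurrence %.2f Hz over %d samples\n",
              x$mean_duration_s, x$mean_occurrence_hz, x$n_samples))
  print(x$per_map)
  invisible(x)
}

#' Tidy microstate metrics into one row per map
#' @param x A `ms_metrics` object.
#' @param ... Unused.
#' @return The per-map tibble.
#' @export
tidy.ms_metrics <- function(x, ...) x$per_map

#' One-row summary of microstate metrics
#' @param x A `ms_metrics` object.
#' @param ... Unused.
#' @return A one-row tibble with the overall mean duration and occurrence.
#' @export
glance.ms_metrics <- function(x, ...) {
  tibble::tibble(mean_duration_s = x$mean_duration_s,
                 mean_occurrence_hz = x$mean_occurrence_hz,
                 n_samples = x$n_samples, fs = x$fs)
}

#' Backfit a map set to an epoch and compute all sequence outputs
#'
#' Convenience wrapper chaining [assign_labels()], [smooth_labels()],
#' [segment_runs()], [ms_metrics()] and [compute_gev()] (GEV is computed on
#' the smoothed labels, which are the labels all metrics use).
#'
#' @inheritParams assign_labels
#' @inheritParams smooth_labels
#' @return A list: `labels` (smoothed), `runs`, `metrics`, `gev`.
#' @export
backfit_epoch <- function(epoch, mapset, window_ms = 30, penalty = 1) {
  lab <- assign_labels(epoch, mapset)
  lab <- smooth_labels(epoch, mapset, lab, window_ms, penalty)
  runs <- segment_runs(lab)
  list(labels = lab, runs = runs,
       metrics = ms_metrics(runs),
       gev = compute_gev(epoch, mapset, lab$labels))
}
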