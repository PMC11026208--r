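# End-to-end orchestration of the two analysis tracks: group-level (group
# maps per age x sleep cell) and individual (per-epoch maps).

#' Analysis configuration
#'
#' Collects every tunable parameter of the pipeline with defaults matching
#' the standard neonatal protocol: 0.2-25 Hz 7th-order zero-phase
#' Butterworth band, resampling to 100 Hz, 5-minute epochs, k searched over
#' 3..15 with 4 maps used for backfitting, 20 k-means restarts, 30 ms / 1.0
#' smoothing, 5000 permutations for each randomization test, and age-group
#' boundaries at 32, 34 and 37 weeks PMA.
#'
#' @param filter_low_hz,filter_high_hz,filter_order Bandpass design.
#' @param resample_hz Analysis sampling rate.
#' @param epoch_s Epoch length in seconds.
#' @param k_min,k_max Search range of the Krzanowski-Lai criterion.
#' @param k_fixed Number of maps used for backfitting and group maps.
#' @param n_restarts k-means restarts.
#' @param smooth_window_ms,smooth_penalty Backfitting smoothing parameters.
#' @param n_perm Permutations for the chi-square and TANOVA tests.
#' @param seed Root seed; all stage seeds derive from it.
#' @param run_kl Whether the individual track also reports the KL-selected k
#'   per epoch (slower; the fixed k is used for metrics either way).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(filter_low_hz = 0.2, filter_high_hz = 25,
                            filter_order = 7L, resample_hz = 100,
                            epoch_s = 300, k_min = 3L, k_max = 15L,
                            k_fixed = 4L, n_restarts = 20L,
                            smooth_window_ms = 30, smooth_penalty = 1,
                            n_perm = 5000L, seed = 1L, run_kl = FALSE) {
  structure(as.list(environment()), class = "analysis_config")
}

cell_id <- function(age_group, sleep_state) paste(age_group, sleep_state, sep = "_")

# preprocess every epoch of a cohort tibble once
preprocess_cohort <- function(cohort, config) {
  purrr::map(cohort$epoch, preprocess_epoch, config = config)
}

# individual maps (fixed k) for a list of preprocessed epochs; the seed is
# shared so identical epochs yield identical maps wherever they appear
individual_mapsets <- function(epochs, config) {
  purrr::map(epochs, function(ep) {
    peaks <- gfp_peaks(global_field_power(ep))
    modified_kmeans(t(ep$data[, peaks, drop = FALSE]), config$k_fixed,
                    n_restarts = config$n_restarts,
                    seed = child_seed(config$seed, 101L))$mapset
  })
}

#' Run the group-level analysis track
#'
#' Per epoch: preprocessing and individual maps. Per age x sleep cell:
#' pooled group-level maps, map order matched across cells, backfitting of
#' the cell's maps onto every member epoch (with smoothing), per-map
#' metrics, GEV, a randomized chi-square syntax test on the pooled run
#' sequence, and paired observed-vs-expected transition tests with FDR
#' control. Pairwise TANOVA compares corresponding maps between cells.
#' Empty cells are reported and skipped with a warning.
#'
#' @param cohort A cohort tibble (see [generate_cohort()]) with columns
#'   `subject_id`, `ga_weeks`, `pma_weeks`, `age_group`, `sleep_state` and
#'   list-column `epoch`.
#' @param config An [analysis_config()].
#' @return A list: `cell_maps` (named list of [ms_mapset()]), `cell_gev`
#'   (tibble), `metrics` (per epoch x map tibble), `syntax` (per-cell
#'   chi-square tibble), `transitions` (per-cell transition test tibble),
#'   `tanova` (pairwise map-similarity tibble), `config`.
#' @export
run_group_analysis <- function(cohort, config = analysis_config()) {
  stopifnot(nrow(cohort) > 0)
  cohort$cell <- cell_id(cohort$age_group, cohort$sleep_state)
  cells <- sort(unique(cohort$cell))
  all_cells <- as.vector(outer(levels(age_group_of(numeric(0))),
                               c("QS", "NQS"), cell_id))
  missing_cells <- setdiff(all_cells, cells)
  if (length(missing_cells) > 0) {
    warning("empty cells skipped: ", paste(missing_cells, collapse = ", "))
  }
  pre <- preprocess_cohort(cohort, config)
  indiv <- individual_mapsets(pre, config)

  cell_maps <- list()
  for (cc in cells) {
    idx <- which(cohort$cell == cc)
    cell_maps[[cc]] <- group_maps(indiv[idx], config$k_fixed,
                                  n_restarts = config$n_restarts,
                                  seed = child_seed(config$seed, 200L +
                                                      match(cc, cells)))
  }
  # common map order across cells, anchored on the first cell
  if (length(cells) > 1L) {
    mm <- match_map_order(cell_maps[[1L]], cell_maps[-1L])
    cell_maps[-1L] <- mm$mapsets
  }

  metrics <- list(); gev_rows <- list(); syntax_rows <- list()
  trans_rows <- list()
  for (cc in cells) {
    idx <- which(cohort$cell == cc)
    maps <- cell_maps[[cc]]
    fits <- purrr::map(idx, function(i) {
      backfit_epoch(pre[[i]], maps, config$smooth_window_ms,
                    config$smooth_penalty)
    })
    gev_rows[[cc]] <- tibble::tibble(
      cell = cc, gev = mean(purrr::map_dbl(fits, "gev")), n_epochs = length(idx))
    metrics[[cc]] <- purrr::map2_dfr(fits, idx, function(f, i) {
      dplyr::mutate(f$metrics$per_map,
                    subject_id = cohort$subject_id[i],
                    pma_weeks = cohort$pma_weeks[i],
                    sleep_state = cohort$sleep_state[i],
                    age_group = as.character(cohort$age_group[i]),
                    cell = cc, gev = f$gev, .before = 1L)
    })
    # pooled run-label sequence across the cell's epochs (the handful of
    # junction transitions is negligible against ~10^3 real ones)
    pooled <- unlist(purrr::map(fits, function(f) f$runs$label))
    syn <- syntax_chisq_test(pooled, config$k_fixed, n_perm = config$n_perm,
                             seed = child_seed(config$seed, 300L +
                                                 match(cc, cells)))
    syntax_rows[[cc]] <- tibble::tibble(cell = cc, chi2 = syn$chi2, p = syn$p,
                                        n_runs = syn$n_runs)
    if (length(idx) >= 3L) {
      per_epoch <- purrr::map(fits, function(f) {
        list(observed = observed_transitions(f$runs, config$k_fixed),
             expected = expected_transitions(f$runs, config$k_fixed))
      })
      trans_rows[[cc]] <- dplyr::mutate(transition_group_test(per_epoch),
                                        cell = cc, .before = 1L)
    }
  }

  tanova_rows <- list()
  if (length(cells) > 1L) {
    pairs <- utils::combn(cells, 2L, simplify = FALSE)
    for (pr in pairs) {
      for (m in seq_len(config$k_fixed)) {
        tv <- tanova_similarity(cell_maps[[pr[1]]]$maps[m, ],
                                cell_maps[[pr[2]]]$maps[m, ],
                                n_perm = config$n_perm,
                                seed = child_seed(config$seed,
                                                  5000L + 17L * m +
                                                    match(pr[1], cells) +
                                                    31L * match(pr[2], cells)))
        tanova_rows[[length(tanova_rows) + 1L]] <- tibble::tibble(
          cell_a = pr[1], cell_b = pr[2], map = m,
          effect_size = tv$effect_size, p = tv$p)
      }
    }
  }

  list(cell_maps = cell_maps,
       cell_gev = dplyr::bind_rows(gev_rows),
       metrics = dplyr::bind_rows(metrics),
       syntax = dplyr::bind_rows(syntax_rows),
       transitions = dplyr::bind_rows(trans_rows),
       tanova = dplyr::bind_rows(tanova_rows),
       config = config)
}

#' Run the individual analysis track
#'
#' Per epoch: preprocessing, individual maps at the configured fixed k
#' (optionally also the KL-selected k, reported but not enforced, so the
#' metric table stays comparable across epochs), backfitting with smoothing,
#' overall mean duration and occurrence, GEV and the Hurst exponent of the
#' label sequence. When at least 3 epochs per sleep state are present, the
#' Pearson associations of each metric with PMA are added.
#'
#' @inheritParams run_group_analysis
#' @return A list: `epochs` (tidy per-epoch metric tibble), `associations`
#'   (tibble or NULL when too few epochs), `long` (long-format export for
#'   external mixed-model fitting), `config`.
#' @export
run_individual_analysis <- function(cohort, config = analysis_config()) {
  stopifnot(nrow(cohort) > 0)
  pre <- preprocess_cohort(cohort, config)
  rows <- purrr::imap(pre, function(ep, i) {
    peaks <- gfp_peaks(global_field_power(ep))
    samples <- t(ep$data[, peaks, drop = FALSE])
    fit <- modified_kmeans(samples, config$k_fixed,
                           n_restarts = config$n_restarts,
                           seed = child_seed(config$seed, 101L))
    k_kl <- NA_integer_
    if (isTRUE(config$run_kl)) {
      k_kl <- tryCatch(
        select_k_kl(samples, config$k_min, config$k_max,
                    n_restarts = config$n_restarts,
                    seed = child_seed(config$seed, 601L))$k_opt,
        error = function(e) NA_integer_)
    }
    bf <- backfit_epoch(ep, fit$mapset, config$smooth_window_ms,
                        config$smooth_penalty)
    tibble::tibble(
      subject_id = cohort$subject_id[i],
      ga_weeks = cohort$ga_weeks[i],
      pma_weeks = cohort$pma_weeks[i],
      sleep_state = cohort$sleep_state[i],
      k_kl = k_kl,
      mean_duration_s = bf$metrics$mean_duration_s,
      mean_occurrence_hz = bf$metrics$mean_occurrence_hz,
      gev = bf$gev,
      hurst = hurst_dfa(bf$labels)
    )
  })
  tab <- dplyr::bind_rows(rows)
  assoc <- NULL
  enough <- tab |>
    dplyr::count(.data$sleep_state) |>
    dplyr::filter(.data$n >= 3L)
  if (nrow(enough) > 0) {
    assoc <- metric_age_association(
      dplyr::semi_join(tab, enough, by = "sleep_state"))
  } else {
    warning("fewer than 3 epochs per sleep state: association skipped")
  }
  list(epochs = tab, associations = assoc,
       long = metrics_long_table(tab), config = config)
}
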