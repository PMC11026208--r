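# ggplot2 helpers for the main result types. Numeric outputs are the
# package's contract; these plots are convenience views.

#' Plot microstate map loadings
#'
#' Channel-by-map tile view of a map set (no scalp geometry is assumed; the
#' analysis is montage-agnostic).
#'
#' @param object A [ms_mapset()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ms_mapset <- function(object, ...) {
  d <- tibble::tibble(
    map = rep(rownames(object$maps), each = ncol(object$maps)),
    channel = factor(rep(colnames(object$maps), times = nrow(object$maps)),
                     levels = colnames(object$maps)),
    loading = as.vector(t(object$maps))
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$channel, .data$map,
                                  fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "loading") +
    ggplot2::theme_minimal()
}

#' Plot a Krzanowski-Lai curve
#'
#' Dispersion W(k) and the KL statistic against k, with the selected k
#' marked.
#'
#' @param kl_result The list returned by [select_k_kl()].
#' @return A ggplot object.
#' @export
plot_kl_curve <- function(kl_result) {
  d <- tidyr::pivot_longer(kl_result$kl, c("W", "kl"),
                           names_to = "quantity", values_to = "value")
  ggplot2::ggplot(dplyr::filter(d, is.finite(.data$value)),
                  ggplot2::aes(.data$k, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = kl_result$k_opt, linetype = 2) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Plot metric-versus-age relationships
#'
#' Scatter of a per-epoch metric against PMA per sleep state with
#' least-squares lines, the view behind correlation-with-age summaries.
#'
#' @param epochs The per-epoch tibble from [run_individual_analysis()].
#' @param metric Metric column name (default `mean_duration_s`).
#' @return A ggplot object.
#' @export
plot_age_association <- function(epochs, metric = "mean_duration_s") {
  ggplot2::ggplot(epochs, ggplot2::aes(.data$pma_weeks, .data[[metric]],
                                       colour = .data$sleep_state)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "PMA (weeks)", y = metric, colour = NULL) +
    ggplot2::theme_minimal()
}
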