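#' Plot a power surface
#'
#' Power of the adjusted test against the adjusted log2 fold change, one
#' line per enriched-profile replicate count, faceted by global-profile
#' replicate count when the allocation is unequal.
#'
#' @param object a `ptm_power_surface` from [power_surface()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ptm_power_surface <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$delta_adj, y = .data$power,
    colour = factor(.data$j_ptm), group = factor(.data$j_ptm)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "adjusted log2 fold change", y = "power",
                  colour = "replicates\n(enriched)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_bw()
  if (length(unique(df$j_protein)) > 1) {
    p <- p + ggplot2::facet_wrap(~j_protein,
                                 labeller = ggplot2::label_both)
  }
  p
}

#' Plot benchmark metrics by method
#'
#' Confusion metrics per method across simulated configurations, one facet
#' per metric; the dashed line marks the nominal FDR level on the eFDR
#' panel.
#'
#' @param object a `ptm_benchmark` from [run_benchmark()].
#' @param metrics which metrics to show.
#' @param alpha nominal FDR level drawn on the eFDR panel.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ptm_benchmark <- function(object,
                                   metrics = c("efdr", "accuracy", "recall"),
                                   alpha = 0.05, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("config", "method", metrics)],
    dplyr::all_of(metrics), names_to = "metric", values_to = "value"
  )
  ref <- tibble::tibble(metric = "efdr", value = alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(data = ref[ref$metric %in% metrics, ],
                        ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
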