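# Figure surfaces: stacked class-percentage bars per region/group and a
# z-score distribution view with the SD-limit bin boundaries.

CLASS_COLOURS <- c(
  overexpressed = "#4daf4a",
  normal = "#377eb8",
  low = "#ffd92f",
  deficient = "#ff7f00",
  severely_deficient = "#e41a1c"
)

#' Stacked class-percentage bars per region and group
#'
#' The classic deficiency surface: one stacked bar per region x group (and
#' ratio panel), coloured by the five classes (overexpressed green, normal
#' blue, low yellow, deficient orange, severely deficient red).
#'
#' @param breakdown A `mito_breakdown` tibble from [aggregate_breakdown()].
#' @return A ggplot.
#' @export
plot_class_breakdown <- function(breakdown) {
  d <- breakdown |>
    mutate(ratio = ifelse(.data$mass == "unity", .data$target,
                          paste0(.data$target, "/", .data$mass)),
           class = factor(.data$class, levels = rev(DEFICIENCY_CLASSES)))
  ggplot2::ggplot(d, ggplot2::aes(.data$group, .data$percentage,
                                  fill = .data$class)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::facet_grid(ratio ~ region) +
    ggplot2::scale_fill_manual(values = CLASS_COLOURS, drop = FALSE) +
    ggplot2::labs(x = NULL, y = "% of neurons", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname plot_class_breakdown
#' @param object A `mito_breakdown`.
#' @param ... Unused.
#' @export
autoplot.mito_breakdown <- function(object, ...) plot_class_breakdown(object)

#' z-score distributions with classification boundaries
#'
#' Boxplots of per-cell z-scores by group (faceted by region) with dashed
#' lines at the -2 / -3 / -4 SD class limits.
#'
#' @param records z-score record tibble from [zscore_cells()].
#' @return A ggplot.
#' @export
plot_zscore_distribution <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(.data$group, .data$z)) +
    ggplot2::geom_hline(yintercept = c(-2, -3, -4), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(x = NULL, y = "z-score (control SD units)") +
    ggplot2::theme_minimal()
}
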