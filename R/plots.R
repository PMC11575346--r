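# ggplot2 views of the main result types.

#' @method autoplot foci_distribution
#' @export
autoplot.foci_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin, y = .data$fraction)) +
    ggplot2::geom_col(fill = "#2b8cbe") +
    ggplot2::labs(
      x = "foci per cell", y = "fraction of cells",
      title = paste0("Focus-count distribution (n = ",
                     attr(object, "n_cells"), " cells)")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a focus-count distribution
#' @param distribution A `foci_distribution` from [summarize_foci()].
#' @return A ggplot object.
#' @export
plot_foci_distribution <- function(distribution) autoplot(distribution)

#' @method autoplot appearance_summary
#' @export
autoplot.appearance_summary <- function(object, ...) {
  df <- object$times |> filter(!.data$appearance_censored)
  ggplot2::ggplot(df, ggplot2::aes(x = "", y = .data$appearance_min)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.15, outlier.shape = NA) +
    ggplot2::geom_hline(yintercept = object$median_appearance,
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "appearance time (min)",
                  title = paste0("Colony appearance times (median ",
                                 object$median_appearance, " min)")) +
    ggplot2::theme_minimal()
}

#' Plot colony appearance times
#' @param summary An `appearance_summary` from [summarize_appearance()].
#' @return A ggplot object.
#' @export
plot_appearance_times <- function(summary) autoplot(summary)

#' @method autoplot tdpa_result
#' @export
autoplot.tdpa_result <- function(object, ...) {
  df <- object$stats |> filter(.data$tested)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$q),
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = object$criteria$log2fc_threshold,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(object$criteria$fdr_threshold),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(
      enriched = "#d7301f", exclusive = "#7b3294", none = "grey60"
    )) +
    ggplot2::labs(x = "log2 fold change (WT / mutant pellet fraction)",
                  y = "-log10 BH q", colour = NULL,
                  title = "Pellet-fraction differential enrichment") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a TdPA analysis
#' @param result A `tdpa_result` from [build_tdpa()].
#' @return A ggplot object.
#' @export
plot_tdpa_volcano <- function(result) autoplot(result)
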