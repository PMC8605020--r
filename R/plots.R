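category_fill <- c(not_expressed = "grey85", lower = "#91bfdb",
                   similar = "#ffffbf", higher = "#d73027",
                   undetermined = "grey55")

#' Per-sample expression profile heatmap of a pipeline run
#'
#' One tile per validated mercury gene and sample, colored by the
#' rpoB-relative expression category, faceted by MAG — the per-sample
#' counterpart of [plot_summed_profile()].
#'
#' @param object A `mercmags_run`.
#' @param families Gene families to show (default: the mercury families).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mercmags_run <- function(object,
                                  families = c("hgcAB", "merA",
                                               "merA_like", "merB"),
                                  ...) {
  df <- filter(object$expression, .data$family %in% families)
  if (nrow(df) == 0) abort("no validated genes to plot")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$gene_id,
                                   fill = .data$category)) +
    ggplot2::geom_tile(color = "white", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = category_fill, drop = FALSE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$mag_id),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, fill = "vs rpoB") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Summed whole-run expression profile per MAG
#'
#' Shows, for each MAG, the ratio of each gene's transcripts summed over
#' all sampling periods to the summed rpoB transcripts, on a log2 axis
#' with the similarity band shaded.
#'
#' @param run A `mercmags_run`.
#' @param families Gene families to show.
#' @return A ggplot object.
#' @export
plot_summed_profile <- function(run, families = c("hgcAB", "merA",
                                                  "merA_like", "merB")) {
  df <- run$summed |>
    filter(.data$family %in% families, !is.na(.data$ratio),
           .data$ratio > 0)
  if (nrow(df) == 0) abort("no summed ratios to plot")
  band <- run$params$similar_band
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mag_id, y = .data$ratio,
                                   color = .data$family)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = band[1], ymax = band[2],
                      alpha = 0.15, fill = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::labs(x = NULL, y = "summed transcript ratio (gene / rpoB)",
                  color = "family") +
    ggplot2::theme_minimal(base_size = 10) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' MAG coverage vs the community average
#'
#' Bar plot of per-MAG coverage (the relative-abundance proxy) with the
#' community mean marked; bars are colored by above/below-average class.
#'
#' @param run A `mercmags_run` (or an [abundance_summary()]).
#' @return A ggplot object.
#' @export
plot_abundance <- function(run) {
  ab <- if (inherits(run, "abundance_summary")) run else run$abundance
  if (is.null(ab)) abort("run has no abundance summary")
  ggplot2::ggplot(ab$mags,
                  ggplot2::aes(x = stats::reorder(.data$mag_id,
                                                  -.data$coverage),
                               y = .data$coverage,
                               fill = .data$abundance_class)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = ab$stats$mean, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(above_average = "#d73027",
                                          below_average = "grey60")) +
    ggplot2::labs(x = NULL, y = "coverage (reads per base)",
                  fill = NULL) +
    ggplot2::theme_minimal(base_size = 10) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
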