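#' Plot a species chromatogram
#'
#' Renders the alpha x p matrix as an array of coloured cells: one labelled
#' column per environmental dimension, category 1 (lowest values) at the
#' bottom, a blue-to-red colormap over standardized abundance in \[0, 1\]
#' (blue = nil or low abundance, red = high), missing categories white.
#'
#' @param object A [chromatogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chromatogram <- function(object, ...) {
  df <- tidy.chromatogram(object)
  df$dimension <- factor(df$dimension, levels = colnames(object$wstar))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dimension, y = .data$category,
                                   fill = .data$abundance)) +
    ggplot2::geom_tile(colour = NA) +
    ggplot2::scale_fill_gradientn(
      colours = c("#2166AC", "#67A9CF", "#D1E5F0", "#FDDBC7", "#EF8A62", "#B2182B"),
      limits = c(0, 1), na.value = "white",
      name = "Standardized\nabundance"
    ) +
    ggplot2::scale_y_continuous(expand = c(0, 0)) +
    ggplot2::labs(
      x = NULL,
      y = paste0("Category (1–", object$params$alpha, ", low → high)"),
      title = if (!is.null(object$species)) object$species else NULL
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1),
                   panel.grid = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Save a chromatogram plot to file
#'
#' @param chrom A [chromatogram()].
#' @param out Output path (extension decides the device, e.g. `.png`,
#'   `.svg`, `.pdf`).
#' @param width,height Plot size in inches.
#' @return `out`, invisibly.
#' @export
plot_chromatogram <- function(chrom, out, width = 6, height = 5) {
  gg <- autoplot.chromatogram(chrom)
  ggplot2::ggsave(out, gg, width = width, height = height)
  invisible(out)
}

#' @importFrom rlang .data
NULL
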