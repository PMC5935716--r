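#' Linear gene-map plot of a gene order
#'
#' Draws the (linearized) gene order as a row of boxes, majority-strand
#' genes above the axis and minority-strand genes below, coloured by gene
#' class.
#'
#' @param object A [gene_order()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gene_order <- function(object, ...) {
  df <- tibble::tibble(
    pos = seq_len(nrow(object)),
    gene = object$gene,
    label = .short_label(object$gene),
    class = gene_class(object$gene),
    strand = factor(
      ifelse(object$orientation > 0, "majority", "minority"),
      levels = c("majority", "minority")
    )
  )
  df$y <- ifelse(df$strand == "majority", 0.5, -0.5)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$y)) +
    ggplot2::geom_tile(
      ggplot2::aes(fill = .data$class),
      width = 0.9, height = 0.9, colour = "grey30"
    ) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.6) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_y_continuous(
      limits = c(-1.2, 1.2),
      breaks = c(-0.5, 0.5), labels = c("minority", "majority")
    ) +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = order_name(object)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      panel.grid = ggplot2::element_blank(),
      axis.text.x = ggplot2::element_blank()
    )
}

#' Plot per-gene rearrangement status
#'
#' @param classification Output of [classify_rearranged()].
#' @return A ggplot object.
#' @export
plot_rearrangement_status <- function(classification) {
  df <- classification
  df$pos <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$pos, y = .data$class,
    fill = .data$status
  )) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(
      values = c(rearranged = "#D55E00", unrearranged = "#888888")
    ) +
    ggplot2::labs(x = "gene position (derived order)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
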