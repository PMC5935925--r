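# ggplot2 views of the main result types.

#' Plot raw tag-count histogram
#'
#' The diagnostic for tag saturation: a mode at 1 (error tags) and a second,
#' broader mode near the designed per-molecule coverage (true tags).
#'
#' @param bins a `tag_bins` object, or its `tag_counts` tibble
#' @return a ggplot
#' @export
plot_tag_histogram <- function(bins) {
  tc <- if (inherits(bins, "tag_bins")) bins$tag_counts else bins
  ggplot2::ggplot(tc, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey35") +
    ggplot2::facet_wrap(~end) +
    ggplot2::labs(x = "times a tag was observed", y = "number of tags",
                  title = "Raw molecular tag counts") +
    ggplot2::theme_minimal()
}

#' Plot rarefaction curves
#'
#' @param object tibble from [rarefaction_curves()]
#' @param ... unused
#' @return a ggplot
#' @export
plot_rarefaction <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$depth,
                                       y = .data$mean_observed,
                                       colour = .data$sample_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "sequences subsampled", y = "observed OTUs",
                  colour = "sample") +
    ggplot2::theme_minimal()
}

#' Plot rank abundance
#'
#' @param object tibble from [rank_abundance()]
#' @param ... unused
#' @return a ggplot
#' @export
plot_rank_abundance <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = stats::reorder(.data$otu_id, .data$rank), y = .data$total)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "OTU (by rank)", y = "sequences") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot per-sample taxon composition
#'
#' @param object tibble from [relative_abundance_by_taxon()]
#' @param ... unused
#' @return a ggplot
#' @export
plot_composition <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sample_id,
                                       y = .data$fraction,
                                       fill = .data$taxon)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "relative abundance", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Stacked-composition autoplot for an OTU table
#' @importFrom ggplot2 autoplot
#' @param object an `otu_tbl`
#' @param ... passed on
#' @return a ggplot
#' @method autoplot otu_tbl
#' @export
autoplot.otu_tbl <- function(object, ...) {
  plot_composition(relative_abundance_by_taxon(object), ...)
}
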