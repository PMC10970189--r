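#' Plot the degree distribution of a network
#'
#' Histogram of node degrees from a centrality table; co-expression networks
#' exported at a TOM cutoff typically show the right-skewed, long-tailed
#' shape expected of approximately scale-free graphs.
#'
#' @param tab A `centrality_table`.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_degree_distribution <- function(tab, bins = 30) {
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$DG)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "degree", y = "genes",
                  title = "Degree distribution") +
    ggplot2::theme_minimal()
}

#' Plot the scale-free fit across candidate soft-threshold powers
#'
#' @param object An `sft_report`.
#' @param ... Unused.
#' @return A ggplot object showing signed R-squared against the candidate
#'   power, with the fit target and the selected power marked.
#' @export
autoplot.sft_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta, y = .data$r_squared)) +
    ggplot2::geom_hline(yintercept = attr(object, "r2_target"),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "soft-threshold power", y = "signed scale-free R²",
                  title = "Soft-threshold selection") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Histogram of differential-correlation z statistics
#'
#' Under the null most z statistics fall in a central normal bulk; planted or
#' real differential pairs appear in the tails. Selected pairs are
#' highlighted when the table carries an `fdr` column and thresholds are
#' given.
#'
#' @param records Pair table from [screen_all_pairs()] / [adjust_fdr()].
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_z_histogram <- function(records, bins = 60) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$z_stat)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey30", colour = "white") +
    ggplot2::labs(x = "Fisher z statistic", y = "gene pairs",
                  title = "Differential correlation z statistics") +
    ggplot2::theme_minimal()
}

#' Plot TF-centred differential modules
#'
#' Shows each transcription factor's partners and the sign and size of the
#' correlation change, one facet per TF.
#'
#' @param modules Output of [build_tf_modules()].
#' @return A ggplot object.
#' @export
plot_tf_modules <- function(modules) {
  ggplot2::ggplot(modules,
                  ggplot2::aes(x = .data$delta_r,
                               y = stats::reorder(.data$partner, .data$delta_r),
                               fill = .data$sign)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$tf), scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(positive = "firebrick",
                                          negative = "navy")) +
    ggplot2::labs(x = expression(Delta * r ~ "(sensitive - tolerant)"),
                  y = "partner gene",
                  title = "Transcription-factor differential modules") +
    ggplot2::theme_minimal()
}
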