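#' Plot per-cell QC summaries
#'
#' Contact totals per cell with the pass threshold, on a log scale.
#' @param qc tibble from [qc_cells()].
#' @param min_pairs threshold line to draw.
#' @return a ggplot object.
#' @export
plot_qc <- function(qc, min_pairs = 1000) {
  ggplot2::ggplot(qc, ggplot2::aes(x = .data$total_pairs,
                                   fill = .data$pass_flag)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(xintercept = min_pairs, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "contacts per cell", y = "cells", fill = "pass") +
    ggplot2::theme_minimal()
}

#' Plot the ecDNA feature triplet by group
#'
#' Violin panels of hub index, trans-to-cis bin ratio and inferred copy,
#' optionally split by a grouping column (e.g. the true amplicon mode).
#' @param features tibble from [build_feature_table()].
#' @param group optional column name to facet by.
#' @return a ggplot object.
#' @export
plot_features <- function(features, group = NULL) {
  long <- features |>
    dplyr::select(dplyr::any_of(c("barcode", "bin", group)),
                  "hub_index", "trans_cis_ratio", "inferred_copy") |>
    tidyr::pivot_longer(c("hub_index", "trans_cis_ratio", "inferred_copy"),
                        names_to = "feature", values_to = "value")
  p <- if (is.null(group)) {
    ggplot2::ggplot(long, ggplot2::aes(x = .data$feature, y = .data$value))
  } else {
    ggplot2::ggplot(long, ggplot2::aes(x = .data[[group]], y = .data$value,
                                       fill = .data[[group]]))
  }
  p + ggplot2::geom_violin(na.rm = TRUE) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Plot per-bin positive-cell fractions from aggregated ecDNA calls
#' @param aggregated list from [aggregate_calls()].
#' @return a ggplot object.
#' @export
plot_call_fractions <- function(aggregated) {
  aggregated$per_bin |>
    tidyr::pivot_longer(dplyr::starts_with("frac_"), names_to = "class",
                        names_prefix = "frac_", values_to = "fraction") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$bin, y = .data$fraction,
                                 colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "global bin", y = "fraction of cells") +
    ggplot2::theme_minimal()
}

#' Training-loss curve of a CNN ecDNA caller
#' @param object a `cnn_model`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot cnn_model
#' @export
autoplot.cnn_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch,
                                             y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training loss") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Two-dimensional state projection plot
#'
#' Cells on the (identity, D) plane coloured by quadrant.
#' @param projection tibble from [state_projection()].
#' @return a ggplot object.
#' @export
plot_state_projection <- function(projection) {
  ggplot2::ggplot(projection,
                  ggplot2::aes(x = .data$identity, y = .data$D,
                               colour = .data$quadrant)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::theme_minimal()
}
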