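# ggplot2 views of the main result types.

#' Volcano plot of a differential signature
#'
#' @param object A [differential_signature()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.de_signature <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$p_adj, 1e-300)),
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                            none = "grey70")) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * attr(object, "lfc_threshold"),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "log2 fold-change", y = "-log10 adjusted p",
                  colour = NULL,
                  title = paste0(attr(object, "group_a"), " vs ",
                                 attr(object, "group_b"))) +
    ggplot2::theme_minimal()
}

#' Significance vs attributable-fraction plot of an MR report
#'
#' @param object An [run_mra()] result.
#' @param label_top Number of top MRs to label.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_report <- function(object, label_top = 10, ...) {
  df <- tibble::as_tibble(object)
  top <- df[df$rank <= label_top, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$attributable_fraction,
                                   y = -log10(pmax(.data$p_adj, 1e-300)))) +
    ggplot2::geom_point(ggplot2::aes(size = .data$regulon_size,
                                     colour = .data$significant), alpha = 0.7) +
    ggplot2::geom_text(data = top, ggplot2::aes(label = .data$tf),
                       vjust = -0.6, size = 3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "grey60")) +
    ggplot2::labs(x = "fraction of signature attributable to MR",
                  y = "-log10 adjusted p", size = "regulon size",
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Cumulative MR-attributable fraction curve
#'
#' @param curve A [cumulative_attribution()] tibble.
#' @return A ggplot object.
#' @export
plot_cumulative_attribution <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$k, y = .data$cumulative_fraction)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "top k MRs (by increasing p)",
                  y = "cumulative fraction of signature covered") +
    ggplot2::theme_minimal()
}

#' Heatmap of TF activity profiles
#'
#' @param object An [infer_activity()] matrix.
#' @param ... Unused.
#' @return A ggplot object (tile heatmap, samples x TFs).
#' @export
autoplot.activity_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$tf,
                                   fill = .data$activity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2980b9", mid = "white", high = "#c0392b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "activity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 6))
}

#' Discovery vs validation regulon fold-change scatter
#'
#' @param cv A [cross_cohort_validation()] result.
#' @return A ggplot object.
#' @export
plot_cross_cohort <- function(cv) {
  ggplot2::ggplot(cv$table, ggplot2::aes(x = .data$mean_lfc_discovery,
                                         y = .data$mean_lfc_validation,
                                         size = .data$regulon_size)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::labs(
      x = "mean regulon log2FC (discovery)",
      y = "mean regulon log2FC (validation)",
      size = "regulon size",
      subtitle = sprintf("Pearson r = %.2f", cv$pearson$estimate)
    ) +
    ggplot2::theme_minimal()
}

#' Nearest-match distance distributions, observed vs scrambled
#'
#' @param result A [scrambled_motif_test()] result.
#' @return A ggplot object comparing the observed proximal fraction with
#'   the scrambled-motif null distribution.
#' @export
plot_motif_validation <- function(result) {
  df <- tibble::tibble(f = result$scrambled_fractions)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = result$f_obs, colour = "#c0392b",
                        linewidth = 1) +
    ggplot2::labs(
      x = "fraction of nearest matches within proximal window",
      y = "scrambled motifs",
      subtitle = sprintf("%s: f_obs = %.3f, empirical p = %.4g",
                         result$motif_id, result$f_obs, result$p_empirical)
    ) +
    ggplot2::theme_minimal()
}
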