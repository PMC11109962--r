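# ggplot2 views of the main result types.

#' MA-style plot of binding dynamics
#'
#' Mean normalized control signal (log10) against the log2 fold change,
#' colored by the dynamic/static call, with the fold-change cutoff drawn.
#'
#' @param dynamics Tibble from [classify_sites()].
#' @param cutoff Cutoff to draw (default 0.5).
#' @return A ggplot object.
#' @export
plot_dynamics <- function(dynamics, cutoff = 0.5) {
  ggplot2::ggplot(dynamics,
                  ggplot2::aes(x = log10(.data$mean_control + 1),
                               y = .data$log2fc, colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = c(-cutoff, cutoff),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(dynamic = "#D55E00",
                                            static = "grey55")) +
    ggplot2::labs(x = "log10 mean normalized control signal",
                  y = "log2 fold change (treated / control)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' TSS-distance distributions by site class
#'
#' @param annotations Tibble from [annotate_sites()].
#' @param labels Tibble `site_id`, `label` from [classify_sites()].
#' @return A ggplot object.
#' @export
plot_tss_distance <- function(annotations, labels) {
  df <- inner_join(annotations, select(labels, "site_id", "label"),
                   by = "site_id") |>
    filter(!is.na(.data$tss_distance))
  ggplot2::ggplot(df, ggplot2::aes(
    x = log10(abs(.data$tss_distance) + 1), fill = .data$label)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::scale_fill_manual(values = c(dynamic = "#D55E00",
                                          static = "grey55")) +
    ggplot2::labs(x = "log10 |distance to nearest TSS| (bp)", y = "density",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Rank-signal curve of enhancer clusters
#'
#' The stitched-cluster ranking with the top tier highlighted -- the
#' hockey-stick view used to call clusters of enhancers.
#'
#' @param clusters Tibble from [rank_enhancers()].
#' @return A ggplot object.
#' @export
plot_enhancer_ranking <- function(clusters) {
  df <- arrange(clusters, .data$total_signal) |>
    mutate(ascending_rank = row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ascending_rank,
                                   y = .data$total_signal,
                                   colour = .data$is_top_tier)) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "#D55E00")) +
    ggplot2::labs(x = "clusters ranked by signal", y = "total signal",
                  colour = "top tier") +
    ggplot2::theme_minimal()
}

#' ROC curve of a trained responsiveness forest
#'
#' Plots the validation-set ROC curve (dynamic as the positive class) of
#' the selected model.
#'
#' @param object A `responsiveness_forest`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.responsiveness_forest <- function(object, ...) {
  vp <- object$validation_predictions
  ord <- order(vp$p_dynamic, decreasing = TRUE)
  pos <- vp$truth[ord] == "dynamic"
  df <- tibble(fpr = c(0, cumsum(!pos) / sum(!pos)),
               tpr = c(0, cumsum(pos) / sum(pos)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "#0072B2") +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("validation ROC (AUC = %.3f)",
                      object$validation_metrics$auc)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
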