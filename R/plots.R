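#' Volcano-style plot of a two-part scan
#'
#' Plots each OTU's dominant effect size against -log10 of its final
#' p-value, coloured by FDR significance when a `q_value` column is present.
#'
#' @param scan Result of [two_part_scan()] (optionally after
#'   [permutation_fdr()]).
#' @param fdr Significance threshold on `q_value` for colouring.
#' @return A ggplot object.
#' @export
plot_twopart <- function(scan, fdr = 0.05) {
  df <- dplyr::filter(scan, !is.na(.data$p_final))
  df$effect <- ifelse(!is.na(df$p_binary) & df$p_binary <= df$p_final,
                      df$beta1, df$beta2)
  df$effect[is.na(df$effect)] <- 0
  df$sig <- if ("q_value" %in% names(df)) df$q_value < fdr else FALSE
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect,
                                   y = -log10(.data$p_final),
                                   colour = .data$sig)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick"),
                                 name = sprintf("q < %.2g", fdr)) +
    ggplot2::labs(x = "dominant-component effect (phenotype units)",
                  y = expression(-log[10]~italic(p)[final])) +
    ggplot2::theme_minimal()
}

#' Heatmap of a co-abundance network's correlation matrix
#'
#' Tiles the SparCC correlation matrix with OTUs ordered by co-abundance
#' group, making the block structure of the CAGs visible.
#'
#' @param object A `co_network` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.co_network <- function(object, ...) {
  ord <- object$cag_labels$otu_id[order(object$cag_labels$cag,
                                        object$cag_labels$otu_id)]
  r <- object$r[ord, ord]
  df <- tidyr::expand_grid(otu_a = factor(ord, levels = ord),
                           otu_b = factor(ord, levels = ord))
  df$r <- as.vector(r)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$otu_a, y = .data$otu_b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "SparCC r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Plot a variance-explained curve
#'
#' Mean validation R-squared against the association p-value threshold,
#' with a +-1 SD ribbon across cross-validation repeats.
#'
#' @param object A `variance_curve` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.variance_curve <- function(object, ...) {
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$mean_R2)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$mean_R2 - .data$sd_R2, 0),
                                      ymax = .data$mean_R2 + .data$sd_R2),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "association p-value threshold",
                  y = expression(mean~validation~R^2)) +
    ggplot2::theme_minimal()
}
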