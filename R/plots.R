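#' Plot regulated-gene counts per species and timepoint
#'
#' Bar panel of up/down regulated gene counts, the standard overview of a
#' multi-species differential-expression time course.
#'
#' @param counts Output of [de_counts()].
#' @return A ggplot object.
#' @export
plot_de_counts <- function(counts) {
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$timepoint, y = .data$n_genes,
                               fill = .data$status)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~species) +
    ggplot2::scale_fill_manual(values = c(up = "firebrick",
                                          down = "steelblue")) +
    ggplot2::labs(x = NULL, y = "regulated genes",
                  title = "Drought-regulated genes (WD/WW)") +
    ggplot2::theme_minimal()
}

#' @rdname merge_modules
#' @param object A `module_set`.
#' @param ... Unused.
#' @export
autoplot.module_set <- function(object, ...) {
  eig <- object$eigengenes
  df <- tibble::as_tibble(eig, rownames = "module") %>%
    tidyr::pivot_longer(-"module", names_to = "sample_id",
                        values_to = "eigengene")
  df$sample_id <- factor(df$sample_id, levels = colnames(eig))
  df$module <- factor(df$module, levels = rev(rownames(eig)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$module,
                                   fill = .data$eigengene)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Module eigengenes across samples") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Plot module-trait correlations as an annotated heatmap
#'
#' @param module_trait Output of [module_trait_correlation()].
#' @return A ggplot object; significant cells are outlined.
#' @export
plot_module_trait <- function(module_trait) {
  ggplot2::ggplot(module_trait,
                  ggplot2::aes(x = .data$trait, y = .data$module,
                               fill = .data$r)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::geom_tile(data = filter(module_trait, .data$significant),
                       fill = NA, colour = "black", linewidth = 0.6) +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$r)), size = 2.6, na.rm = TRUE) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Module-trait correlations",
                  subtitle = "outlined cells pass the FDR threshold") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot rosette growth trajectories by treatment
#'
#' Mean projected rosette area over time per species and watering arm, on a
#' log scale so early divergence is visible.
#'
#' @param series A growth series tibble (see [simulate_growth()]).
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(series) {
  summ <- series %>%
    group_by(.data$species, .data$treatment, .data$day) %>%
    summarise(mean_area = mean(.data$area), sd_area = sd(.data$area),
              .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$day, y = .data$mean_area,
                                     colour = .data$treatment)) +
    ggplot2::geom_line() +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_area - .data$sd_area,
      ymax = .data$mean_area + .data$sd_area,
      fill = .data$treatment), alpha = 0.2, colour = NA) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "days after watering stop",
                  y = expression("projected rosette area (mm"^2 * ")"),
                  title = "Rosette growth under well-watered vs water-deficit") +
    ggplot2::theme_minimal()
}
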