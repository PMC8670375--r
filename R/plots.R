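#' Volcano plot of differential abundance
#'
#' Log2 difference (induced minus control) against -log10(p), colored by
#' significance, faceted by strain and fraction.
#'
#' @param diff A `diff_abund` tibble.
#' @return A ggplot object.
#' @export
plot_volcano <- function(diff) {
  ggplot2::ggplot(as_tibble(diff),
                  ggplot2::aes(x = .data$difference, y = .data$neglog10_p,
                               color = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "firebrick")) +
    ggplot2::facet_grid(strain ~ fraction) +
    ggplot2::labs(x = "log2 difference (induced - control)",
                  y = "-log10(p)", color = "significant") +
    ggplot2::theme_bw()
}

#' Replicate PCA plot with confidence ellipses
#'
#' @param pca An `lfq_pca` object from [pca_qc()].
#' @return A ggplot object.
#' @export
plot_pca <- function(pca) {
  ell <- pca$ellipses %>% filter(!.data$degenerate)
  ell_pts <- if (nrow(ell) > 0) {
    theta <- seq(0, 2 * pi, length.out = 100)
    bind_rows(purrr::pmap(ell, function(condition, cx, cy, a, b, angle, ...) {
      tibble(condition = condition,
             PC1 = cx + a * cos(theta) * cos(angle) -
               b * sin(theta) * sin(angle),
             PC2 = cy + a * cos(theta) * sin(angle) +
               b * sin(theta) * cos(angle))
    }))
  } else tibble(condition = character(), PC1 = double(), PC2 = double())
  ggplot2::ggplot(pca$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               color = .data$condition)) +
    ggplot2::geom_path(data = ell_pts, linetype = "dotted") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * pca$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)",
                  100 * (if (length(pca$var_explained) >= 2)
                    pca$var_explained[2] else 0))) +
    ggplot2::theme_bw()
}

#' Mirrored per-group regulation tally plot
#'
#' Upregulated and ON counts point up; downregulated and OFF counts are
#' mirrored downwards, one panel per strain.
#'
#' @param tally Output of [tally_regulation()].
#' @return A ggplot object.
#' @export
plot_tally <- function(tally) {
  long <- tally %>%
    select("group", "strain", "n_up", "n_on", "n_down", "n_off") %>%
    tidyr::pivot_longer(-c("group", "strain"),
                        names_to = "class", values_to = "n") %>%
    mutate(n = dplyr::if_else(.data$class %in% c("n_down", "n_off"),
                              -.data$n, as.double(.data$n)),
           class = factor(.data$class,
                          levels = c("n_on", "n_up", "n_down", "n_off"),
                          labels = c("ON", "up", "down", "OFF")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$n,
                                     fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~strain) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "proteins (down/OFF mirrored)") +
    ggplot2::theme_bw()
}

#' TAU time-course plot per strain
#'
#' @param tau_summary A `tau_summary` from [summarize_tau()].
#' @return A ggplot object.
#' @export
plot_tau <- function(tau_summary) {
  ggplot2::ggplot(tau_summary$profile,
                  ggplot2::aes(x = .data$time_min / 60, y = .data$mean_tau,
                               color = .data$strain, fill = .data$strain)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_tau - .data$sd_tau,
                                      ymax = .data$mean_tau + .data$sd_tau),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "TAU (arbitrary units)") +
    ggplot2::theme_bw()
}
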