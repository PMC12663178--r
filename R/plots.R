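# Publication-style figures for the staged analysis. All take the tabular
# results, so they work identically for synthetic and measured cohorts.

save_fig <- function(p, path, width = 6, height = 4.5) {
  grDevices::pdf(path, width = width, height = height)
  print(p)
  grDevices::dev.off()
  invisible(path)
}

#' Final intensity versus distance with the fitted radial law
#'
#' @param fits Tibble from [fit_uptake()] with `gamma`, `I_final`, `converged`.
#' @param law A fitted [radial_law()].
#' @return A ggplot object.
#' @export
plot_radial_law <- function(fits, law) {
  df <- fits[fits$converged, ]
  gg <- seq(max(min(df$gamma), 0.05), max(df$gamma), length.out = 200)
  curve <- data.frame(gamma = gg, I_final = predict(law, gg))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gamma, y = .data$I_final)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6, colour = "firebrick") +
    ggplot2::geom_line(data = curve, colour = "darkgreen", linewidth = 1) +
    ggplot2::labs(x = expression(gamma), y = expression(I[final] ~ "(AU)"),
                  title = sprintf("I_final(gamma) = %.0f + %.0f/gamma  (R^2 = %.2f)",
                                  law$a_AU, law$b_AU, law$r_squared)) +
    ggplot2::theme_minimal()
}

#' Histogram of fitted uptake rate constants
#'
#' @param fits Tibble from [fit_uptake()].
#' @param pop Optional [population_k_stats()] result for the annotation.
#' @return A ggplot object.
#' @export
plot_k_histogram <- function(fits, pop = NULL) {
  df <- fits[fits$converged, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = expression(k ~ (s^{-1})), y = "cells") +
    ggplot2::theme_minimal()
  if (!is.null(pop)) {
    p <- p + ggplot2::geom_vline(xintercept = pop$mean_k, colour = "darkgreen") +
      ggplot2::ggtitle(sprintf("k = %.4g +/- %.4g 1/s (tau = %.1f s, n = %d)",
                               pop$mean_k, pop$sd_k, pop$tau_char, pop$n_used))
  }
  p
}

#' Saturation fit for a single cell
#'
#' @param traces A [trace_set()].
#' @param fits Tibble from [fit_uptake()].
#' @param cell_id Cell to show; default: the converged cell with median
#'   I_final.
#' @return A ggplot object.
#' @export
plot_single_cell <- function(traces, fits, cell_id = NULL) {
  ok <- fits[fits$converged, ]
  if (is.null(cell_id)) {
    cell_id <- ok$cell_id[order(ok$I_final)][ceiling(nrow(ok) / 2)]
  }
  i <- match(cell_id, traces$cells$cell_id)
  f <- fits[fits$cell_id == cell_id, ]
  df <- data.frame(t = traces$time_s, I = traces$intensities[i, ])
  df$pred <- f$I_final * (1 - exp(-f$k * df$t))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$I), size = 0.4, colour = "darkorange") +
    ggplot2::geom_line(ggplot2::aes(y = .data$pred), colour = "darkgreen", linewidth = 1) +
    ggplot2::labs(x = "time since cavitation (s)", y = "I (AU)",
                  title = sprintf("cell %s: I_final = %.0f AU, k = %.4g 1/s, R^2 = %.3f",
                                  cell_id, f$I_final, f$k, f$r_squared)) +
    ggplot2::theme_minimal()
}

#' Heatmaps of the spatiotemporal model fields
#'
#' Shows I(gamma, t), relative permeability P/p0 and damage fraction S_p
#' side by side over the gamma x time grid.
#'
#' @param fields A `field_map` from [compute_field_map()].
#' @return A ggplot object (faceted).
#' @export
plot_field_map <- function(fields) {
  long <- rbind(
    data.frame(gamma = fields$gamma, t_s = fields$t_s, value = fields$I, what = "I (AU)"),
    data.frame(gamma = fields$gamma, t_s = fields$t_s, value = fields$P_over_p0, what = "P / p0"),
    data.frame(gamma = fields$gamma, t_s = fields$t_s, value = fields$S_p, what = "S_p")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_s, y = .data$gamma, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~what, scales = "free") +
    ggplot2::scale_fill_viridis_c(name = NULL) +
    ggplot2::labs(x = "time since cavitation (s)", y = expression(gamma)) +
    ggplot2::theme_minimal()
}
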