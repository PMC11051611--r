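#' Plot a nightscape raster
#'
#' @param object An [ntl_raster].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ntl_raster <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno",
                                  name = "nW cm⁻² sr⁻¹") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Setting-wise mean exposures with confidence intervals
#'
#' Dot-and-interval display of the mean measured exposure per setting label
#' and community (mean of the per-participant values, with a normal 95%
#' interval), the summary view of the 40 measurement groups.
#'
#' @param emat Exposure matrix from [exposure_matrix()].
#' @return A ggplot.
#' @export
plot_exposure_means <- function(emat) {
  sm <- emat |>
    dplyr::group_by(.data$label, .data$community) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(sm, ggplot2::aes(.data$label, .data$mean,
                                   colour = .data$community)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - 1.96 * .data$se,
                                          ymax = .data$mean + 1.96 * .data$se),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = NULL,
                  y = "mean exposure (nW cm⁻² sr⁻¹)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' Forest plot of the logistic health battery
#'
#' Log-odds effect of each exposure setting on the dichotomised health
#' outcome, with Wald 95% confidence intervals, one panel per community.
#'
#' @param battery Result of [run_health_battery()].
#' @return A ggplot.
#' @export
plot_health_forest <- function(battery) {
  ggplot2::ggplot(battery,
                  ggplot2::aes(.data$logit, .data$label,
                               colour = .data$p < 0.05)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::facet_wrap(~community) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick"),
                                 name = "p < 0.05") +
    ggplot2::labs(x = "log-odds of good health per 100 units of exposure",
                  y = NULL) +
    ggplot2::theme_minimal()
}
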