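#' Plot simple slopes of a reaction-time moderation model
#'
#' Draws the fitted regression lines of (standardized) preference on a
#' naturalness component at fast (mean - `band` SD), average, and slow
#' (mean + `band` SD) reaction times.
#'
#' @param fit an `interaction_fit` from [rt_interaction_model()].
#' @param band RT band half-width in SD units.
#' @return A ggplot object.
#' @export
plot_simple_slopes <- function(fit, band = 1.5) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_simple_slopes requires ggplot2")
  }
  ss <- simple_slopes(fit, band = band)
  grid <- expand.grid(component = c(-2, 2), rt_level = ss$rt_level,
                      stringsAsFactors = FALSE)
  grid <- merge(grid, ss, by = "rt_level")
  grid$preference <- grid$slope * grid$component
  grid$rt_level <- factor(grid$rt_level, levels = c("fast", "average", "slow"))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$component,
                                     y = .data$preference,
                                     colour = .data$rt_level)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = paste(fit$component, "naturalness (z)"),
                  y = "preference (z)", colour = "RT") +
    ggplot2::theme_minimal()
}
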