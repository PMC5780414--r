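#' Plot a station rate profile
#'
#' Simple depth-profile plot (depth increasing downward) of one or more
#' rate variables of a station. Requires ggplot2.
#'
#' @param profile A [station_profile()].
#' @param variables Rate columns to draw.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, variables = c("abd", "php", "pr")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_profile() needs the ggplot2 package", call. = FALSE)
  }
  stopifnot(inherits(profile, "station_profile"))
  vars <- intersect(variables, names(profile$samples))
  long <- tidyr::pivot_longer(
    profile$samples[c("depth_m", vars)], cols = dplyr::all_of(vars),
    names_to = "variable", values_to = "rate")
  ggplot2::ggplot(long[!is.na(long$rate), ],
                  ggplot2::aes(x = .data$rate, y = .data$depth_m,
                               colour = .data$variable)) +
    ggplot2::geom_path() +
    ggplot2::geom_point() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "rate (ug C m-3 d-1)", y = "depth (m)",
                  title = profile$station_id) +
    ggplot2::theme_minimal()
}
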