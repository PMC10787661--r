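#' CFC class colours
#'
#' The conventional rainbow colour order for the seven classes: red,
#' orange, yellow, green, blue, dark blue, grey.
#' @export
cfc_colors <- c(
  EXCELLENT = "#D7191C", ADEQUATE = "#F57C00", MILD = "#FFD700",
  MODERATE = "#2E7D32", SEVERE = "#1E5AA8", STEAL = "#0B2161",
  SCAR = "#9E9E9E"
)

#' Polar rainbow plot of a CFC map
#'
#' Renders the classified polar map with apex at the centre and base at the
#' rim, coloured by CFC class.
#'
#' @param object A `cfc_map` from [build_cfc_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cfc_map
#' @export
autoplot.cfc_map <- function(object, ...) {
  df <- dplyr::mutate(object,
                      angle = (.data$sector + 0.5) * 360 /
                        (max(.data$sector) + 1))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$angle, y = .data$ring,
                                   fill = .data$cfc_class)) +
    ggplot2::geom_tile(width = 360 / (max(df$sector) + 1), height = 1) +
    ggplot2::coord_polar(theta = "x") +
    ggplot2::scale_fill_manual(values = cfc_colors, drop = FALSE,
                               name = "CFC class") +
    ggplot2::theme_void() +
    ggplot2::labs(title = unique(df$patient_id)[1])
}

#' Cumulative severity histogram plot
#'
#' @param object A `severity_histogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot severity_histogram
#' @export
autoplot.severity_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cfc_class)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$fraction,
                                   fill = .data$cfc_class)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative, group = 1)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative)) +
    ggplot2::scale_fill_manual(values = cfc_colors, guide = "none") +
    ggplot2::labs(x = NULL, y = "fraction of LV") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot of paired probability estimates
#'
#' @param x,y Paired probability vectors (`x - y` is plotted).
#' @return A ggplot object with bias and limits of agreement.
#' @export
plot_bland_altman <- function(x, y) {
  ba <- bland_altman(x, y)
  df <- tibble::tibble(mean = (x + y) / 2, diff = x - y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = ba$bias, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(ba$lower_loa, ba$upper_loa),
                        linetype = "dashed") +
    ggplot2::labs(x = "mean of pair", y = "difference") +
    ggplot2::theme_minimal()
}
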