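# ggplot2 presentation methods for the main result types.

#' @export
autoplot.medras_kinetics <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[c("time", "n_phys_total", "n_foci")],
    -"time", names_to = "measure", values_to = "count")
  df$measure <- factor(df$measure, c("n_phys_total", "n_foci"),
                       c("physical breaks", "visible foci"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$count,
                                   linetype = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time after exposure start (h)", y = "breaks per cell",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dose_response <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$dose_gy, .data$s_total)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "dose (Gy)", y = "surviving fraction") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.damage_pattern <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$x, .data$y, colour = .data$complex)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", colour = "complex break") +
    ggplot2::theme_minimal()
}

#' Kinetics / dose-response plot helpers
#'
#' Convenience wrappers around the `autoplot()` methods.
#'
#' @param x A `medras_kinetics` or `dose_response` object.
#' @param ... Passed to `autoplot()`.
#' @return A ggplot object.
#' @export
plot_kinetics <- function(x, ...) autoplot.medras_kinetics(x, ...)

#' @rdname plot_kinetics
#' @export
plot_dose_response <- function(x, ...) autoplot.dose_response(x, ...)
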