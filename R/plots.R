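# ggplot2 views of the main result types.

#' @describeIn lattice_solve Coverage profiles per species.
#' @param object A `lattice_solution`.
#' @export
autoplot.lattice_solution <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$coverage,
                                   colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (bp)", y = "coverage c(g, n)",
                  colour = "species") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_nrl Peak ladder with the fitted line whose slope is the
#'   NRL.
#' @param object An `nrl_estimate`.
#' @export
autoplot.nrl_estimate <- function(object, ...) {
  df <- tibble(index = seq_along(object$peaks) - 1, position = object$peaks)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$position)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$nrl,
                         linetype = "dashed") +
    ggplot2::labs(x = "peak index", y = "peak position (bp)",
                  title = sprintf("NRL = %.1f bp", object$nrl)) +
    ggplot2::theme_minimal()
}

#' @describeIn detrend_fourier_period Power spectrum (or autocorrelation)
#'   with the dominant period marked.
#' @param object A `periodicity_result`.
#' @export
autoplot.periodicity_result <- function(object, ...) {
  if (!is.null(object$spectrum) && nrow(object$spectrum %||% tibble())) {
    p <- ggplot2::ggplot(object$spectrum,
                         ggplot2::aes(x = .data$period, y = .data$power)) +
      ggplot2::geom_line() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "period (bp)", y = "spectral power")
  } else {
    p <- ggplot2::ggplot(object$autocorrelation,
                         ggplot2::aes(x = .data$lag, y = .data$value)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "lag (bp)", y = "autocorrelation")
  }
  if (!is.na(object$period)) {
    p <- p + ggplot2::geom_vline(xintercept = object$period,
                                 linetype = "dashed", colour = "red")
  }
  p + ggplot2::theme_minimal()
}

#' @describeIn extract_profile_matrix Occupancy heat map (anchors by
#'   offset).
#' @param object A `profile_matrix`.
#' @export
autoplot.profile_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$anchor,
                                   fill = .data$occupancy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "offset from anchor (bp)", y = "anchor") +
    ggplot2::theme_minimal()
}

#' Aggregate profile line plot
#'
#' @param x A `profile_matrix`.
#' @return A ggplot object of the anchor-averaged occupancy.
#' @export
plot_average_profile <- function(x) {
  stopifnot(inherits(x, "profile_matrix"))
  ggplot2::ggplot(x$average, ggplot2::aes(x = .data$offset,
                                          y = .data$occupancy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "offset from anchor (bp)",
                  y = "normalized occupancy") +
    ggplot2::theme_minimal()
}

#' NRL scan plot
#'
#' @param scan A tibble from [scan_nrl()].
#' @param xlab Parameter axis label.
#' @return A ggplot object of NRL against the scanned parameter.
#' @export
plot_nrl_scan <- function(scan, xlab = "parameter") {
  stopifnot(is.data.frame(scan))
  ggplot2::ggplot(dplyr::filter(scan, .data$ok),
                  ggplot2::aes(x = .data$parameter, y = .data$nrl)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = xlab, y = "NRL (bp)") +
    ggplot2::theme_minimal()
}
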