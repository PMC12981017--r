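#' Plot a free-energy landscape
#'
#' @param object A `fes_landscape`.
#' @param ... Unused.
#' @return A ggplot: tile map of dG (kT) over (PC1, PC2); unvisited bins
#'   blank.
#' @export
autoplot.fes_landscape <- function(object, ...) {
  g <- dplyr::filter(object$grid, !is.na(.data$delta_g_kT))
  ggplot2::ggplot(g, ggplot2::aes(.data$pc1_center, .data$pc2_center,
                                  fill = .data$delta_g_kT)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(Delta * G ~ (k[B] * T)),
                                  direction = -1) +
    ggplot2::labs(x = "PC1 (nm)", y = "PC2 (nm)") +
    ggplot2::theme_minimal()
}

#' Plot a difference CD spectrum
#'
#' Positive/negative contributions relative to the bare-nanocluster
#' reference are shaded red/blue; the band of interest is delimited by
#' dashed lines.
#'
#' @param object A `difference_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.difference_spectrum <- function(object, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$wavelength_nm, .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_area(data = dplyr::mutate(d, delta = pmax(.data$delta, 0)),
                       fill = "firebrick", alpha = 0.4) +
    ggplot2::geom_area(data = dplyr::mutate(d, delta = pmin(.data$delta, 0)),
                       fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$band, linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::labs(x = "wavelength (nm)",
                  y = "hybrid - bare CD intensity (arb.)") +
    ggplot2::theme_minimal()
  p
}

#' Plot contact-number series with the bound threshold
#'
#' @param series A [contact_series()] tibble.
#' @param threshold NOC threshold drawn as a dashed line (default 5).
#' @return A ggplot faceted by analyte, coloured by replica.
#' @export
plot_contact_series <- function(series, threshold = 5) {
  ggplot2::ggplot(series, ggplot2::aes(.data$time_ns, .data$noc,
                                       colour = factor(.data$replica))) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::facet_wrap(~analyte_id) +
    ggplot2::labs(x = "time (ns)", y = "number of contacts",
                  colour = "replica") +
    ggplot2::theme_minimal()
}
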