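#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_tile geom_hline
#'   scale_x_log10 scale_fill_viridis_c labs facet_wrap theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a power spectral density
#'
#' @param object A `qs_psd` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qs_psd <- function(object, ...) {
  ggplot(object, aes(x = .data$frequency, y = .data$level_db)) +
    geom_line(linewidth = 0.3) +
    scale_x_log10() +
    labs(x = "Frequency (Hz)", y = "PSD (dB SPL/Hz)") +
    theme_minimal()
}

#' Plot an excitation pattern, optionally against a hearing threshold
#'
#' @param object A `qs_excitation` tibble.
#' @param profile Optional [species_profile()] whose threshold curve is
#'   overlaid.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qs_excitation <- function(object, profile = NULL, ...) {
  p <- ggplot(object, aes(x = .data$frequency, y = .data$excitation_db)) +
    geom_line(colour = "steelblue") +
    scale_x_log10() +
    labs(x = "Center frequency (Hz)", y = "Excitation (dB SPL)",
         title = object$species[1]) +
    theme_minimal()
  if (!is.null(profile)) {
    thr <- tibble(frequency = object$frequency,
                  threshold = threshold_at(profile, object$frequency))
    p <- p + geom_line(data = thr,
                       aes(x = .data$frequency, y = .data$threshold),
                       colour = "black")
  }
  p
}

#' Plot exceedance of the hearing threshold
#'
#' @param object A `qs_exceedance` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qs_exceedance <- function(object, ...) {
  ggplot(object, aes(x = .data$frequency, y = .data$exceedance_db)) +
    geom_line() +
    geom_hline(yintercept = 0, linetype = "dashed") +
    scale_x_log10() +
    labs(x = "Frequency (Hz)", y = "Excitation - threshold (dB)",
         title = object$species[1]) +
    theme_minimal()
}

#' Plot frequency-response-area matrices
#'
#' One tile panel per ROI: mean dF/F over the frequency-by-level grid.
#'
#' @param object An `fra_matrix` from [build_fra()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fra_matrix <- function(object, ...) {
  ggplot(object$cells,
         aes(x = factor(round(.data$frequency)), y = factor(.data$level),
             fill = .data$mean)) +
    geom_tile() +
    facet_wrap(~roi) +
    scale_fill_viridis_c(name = "mean dF/F") +
    labs(x = "Frequency (Hz)", y = "Level (dB SPL)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 5))
}

#' Plot a scan-design table
#'
#' Frame rate versus line time with the dark-periphery fraction mapped to
#' point size, over candidate DvCL focal lengths.
#'
#' @param design Tibble from [scan_design_table()].
#' @return A ggplot.
#' @export
plot_scan_design <- function(design) {
  ggplot(design, aes(x = .data$line_time_s * 1e6,
                     y = .data$frame_rate_hz)) +
    ggplot2::geom_point(aes(size = .data$dark_fraction)) +
    geom_line(linetype = "dotted") +
    labs(x = "Line time (us)", y = "Frame rate (fps)",
         size = "Dark fraction") +
    theme_minimal()
}
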