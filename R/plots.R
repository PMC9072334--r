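#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_point
#'   geom_col geom_hline geom_ribbon scale_fill_viridis_c labs theme_minimal
#'   facet_wrap coord_equal
NULL

#' @export
ggplot2::autoplot

#' Plot a spatial rate map
#'
#' @param object A [build_rate_map()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rate_map <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$x, y = .data$y, fill = .data$rate)) +
    geom_raster() +
    scale_fill_viridis_c(na.value = "white") +
    coord_equal() +
    labs(x = "x (cm)", y = "y (cm)", fill = "rate (Hz)",
         title = sprintf("peak %.1f Hz, mean %.2f Hz",
                         max(d$rate, na.rm = TRUE), object$lambda_mean)) +
    theme_minimal()
}

#' Plot a speed-amplitude profile
#'
#' Percent change of band (or per-frequency) amplitude relative to
#' immobility, as a function of running speed.
#'
#' @param object A `speed_profile` tibble from
#'   [speed_amplitude_profile()] or [band_speed_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.speed_profile <- function(object, ...) {
  if ("band" %in% names(object)) {
    ggplot(object, aes(x = .data$speed_mid, y = .data$pct_change,
                       colour = .data$band)) +
      geom_hline(yintercept = 0, linetype = 2) +
      geom_line() + geom_point() +
      labs(x = "running speed (cm/s)", y = "amplitude change (%)",
           colour = "band") +
      theme_minimal()
  } else {
    ggplot(object, aes(x = .data$freq, y = .data$speed_mid,
                       fill = .data$pct_change)) +
      geom_raster() +
      scale_fill_viridis_c() +
      labs(x = "frequency (Hz)", y = "running speed (cm/s)",
           fill = "% change") +
      theme_minimal()
  }
}

#' Plot per-window PSDs summarized across windows
#'
#' @param psd_tbl A [psd_windows()] tibble (optionally pre-filtered).
#' @param stat `"median"` or `"mean"` across windows.
#' @param log Use log10 axes.
#' @return A ggplot.
#' @export
plot_psd <- function(psd_tbl, stat = c("median", "mean"), log = TRUE) {
  stat <- match.arg(stat)
  d <- summarize_psd(psd_tbl)
  d$value <- d[[stat]]
  p <- ggplot(d[d$freq > 0, ], aes(x = .data$freq, y = .data$value)) +
    geom_line() +
    labs(x = "frequency (Hz)", y = sprintf("%s PSD (uV^2/Hz)", stat)) +
    theme_minimal()
  if (log) p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}

#' Plot a population phase-rate curve
#'
#' @param curve A [phase_rate_curve()] result.
#' @return A ggplot of mean +/- s.e.m. normalized rate per phase bin.
#' @export
plot_phase_rate_curve <- function(curve) {
  d <- curve$population
  ggplot(d, aes(x = .data$phase_center, y = .data$mean)) +
    geom_ribbon(aes(ymin = .data$mean - .data$sem,
                    ymax = .data$mean + .data$sem), alpha = 0.3) +
    geom_line() +
    geom_hline(yintercept = 1, linetype = 2) +
    labs(x = "oscillation phase (rad)", y = "normalized rate") +
    theme_minimal()
}
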