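#' Canonical CA1 frequency bands
#'
#' Frequency bands used throughout the package, defined by the sign of the
#' relationship between band amplitude and running speed: delta and beta
#' amplitude decrease with speed, theta and gamma increase. The ripple band
#' carries no speed coupling and is used for sharp-wave-ripple detection.
#'
#' The beta band is bounded below at 20 Hz (rather than 10 Hz) to avoid
#' contamination by the first theta harmonic.
#'
#' @return A tibble with columns `band`, `low`, `high` (Hz) and `coupling`
#'   (+1 amplitude increases with running speed, -1 decreases, NA not
#'   speed-defined).
#' @examples
#' canonical_bands()
#' @export
canonical_bands <- function() {
  tibble::tibble(
    band     = c("delta", "theta", "beta", "gamma", "ripple"),
    low      = c(1, 6, 20, 35, 120),
    high     = c(5, 11, 30, 100, 240),
    coupling = c(-1, 1, -1, 1, NA)
  )
}

#' Analysis defaults
#'
#' All tunable parameters of the pipeline in one place, with the values used
#' by every stage unless overridden: spatial binning and smoothing, shuffle
#' counts and minimum time shift, ripple detection thresholds, low-theta
#' episode criterion, cell-type rate cutoff, object-circle radius, and the
#' window lengths used for speed, spectral, exploration, and event-rate
#' analysis.
#'
#' @return A named list of defaults.
#' @examples
#' degu_defaults()$bin_side_cm
#' @export
degu_defaults <- function() {
  list(
    arena_side_cm        = 90,
    rest_side_cm         = 30,
    tracking_rate_hz     = 50,
    lfp_rate_hz          = 2000,
    speed_window_s       = 0.2,
    tracking_gap_s       = 0.5,
    bin_side_cm          = 2.5,
    smooth_sd_bins       = 1.6,
    min_shift_s          = 30,
    n_shuffles_spatial   = 1000,
    n_shuffles_phase     = 100,
    percentiles          = c(95, 99),
    rate_cutoff_hz       = 7,
    object_radius_cm     = 10,
    exploration_window_s = 30,
    psd_window_s         = 2,
    event_window_s       = 60,
    speed_cutoff_slow    = 5,
    speed_cutoff_swr     = 1,
    speed_bin_width      = 2.5,
    speed_max            = 30,
    morlet_cycles        = 6,
    swr_band_hz          = c(120, 240),
    swr_threshold_sd     = 5,
    swr_min_spacing_s    = 0.5,
    low_theta_freqs_hz   = c(8, 6),
    low_theta_smooth_s   = 15,
    low_theta_ratio      = 1.4
  )
}
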