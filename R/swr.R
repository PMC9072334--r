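#' Episodes of prolonged low theta amplitude
#'
#' Sharp waves themselves have spectral content overlapping the theta band,
#' so instantaneous theta amplitude cannot gate ripple detection. Instead,
#' the criterion compares smoothed wavelet amplitudes at two fixed
#' frequencies: episodes are maximal runs where the 8 Hz amplitude does not
#' exceed the 6 Hz amplitude by more than 40% (ratio threshold 1.4), both
#' amplitudes smoothed with a centered 15 s moving average (reflection
#' padding at the record edges). The criterion is a ratio, so it is
#' invariant to overall LFP gain.
#'
#' @param x An [lfp_signal()].
#' @param freqs Length-2 wavelet frequencies `c(num, den)` in Hz (8, 6).
#' @param smooth_window Moving-average window in seconds (15).
#' @param ratio_threshold Maximum allowed amplitude ratio (1.4).
#' @return Object of class `low_theta_episodes`: list with `intervals`
#'   (tibble `start`, `end` in seconds, half-open), `ratio` (tibble `time`,
#'   `ratio`, decimated to ~50 Hz for inspection), `threshold`.
#' @export
low_theta_episodes <- function(x, freqs = c(8, 6), smooth_window = 15,
                               ratio_threshold = 1.4) {
  stopifnot(inherits(x, "lfp"))
  if (lfp_duration(x) <= smooth_window) {
    abort("Record shorter than the smoothing window.",
          class = "degumap_parameter_error")
  }
  sf <- morlet_transform(x, freqs)
  k <- round(smooth_window * x$rate)
  a_num <- moving_average(sf$amplitude[1, ], k)
  a_den <- moving_average(sf$amplitude[2, ], k)
  ratio <- a_num / pmax(a_den, .Machine$double.eps)
  low <- ratio <= ratio_threshold
  runs <- rle(low)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values
  times <- lfp_times(x)
  intervals <- tibble(
    start = times[starts[keep]],
    end = times[ends[keep]] + 1 / x$rate
  )
  dec <- max(1L, round(x$rate / 50))
  idx <- seq(1, length(times), by = dec)
  structure(
    list(intervals = intervals,
         ratio = tibble(time = times[idx], ratio = ratio[idx]),
         threshold = ratio_threshold, freqs = freqs,
         smooth_window = smooth_window),
    class = "low_theta_episodes"
  )
}

#' @export
print.low_theta_episodes <- function(x, ...) {
  cat(sprintf("<low_theta_episodes> %d episode(s), %.1f s total (ratio %g Hz / %g Hz <= %g)\n",
              nrow(x$intervals), sum(x$intervals$end - x$intervals$start),
              x$freqs[1], x$freqs[2], x$threshold))
  invisible(x)
}

in_intervals <- function(t, intervals) {
  if (nrow(intervals) == 0) return(rep(FALSE, length(t)))
  i <- findInterval(t, intervals$start)
  i >= 1 & t < intervals$end[pmax(i, 1)]
}

#' Detect sharp-wave-ripple events
#'
#' Candidate events are local maxima of the Hilbert envelope of the
#' ripple-band (120-240 Hz) LFP exceeding the envelope mean by
#' `threshold_sd` standard deviations (baseline over the whole record, or
#' restricted to the low-theta episodes with `baseline = "episodes"`).
#' Candidates outside low-theta episodes are discarded, and within
#' `min_spacing` seconds only the largest peak is kept (greedy by
#' descending amplitude, so the rule is order-independent).
#'
#' @param x An [lfp_signal()].
#' @param episodes A [low_theta_episodes()] result computed on the same
#'   record, or NULL to skip the gating (all candidates kept).
#' @param band Ripple band in Hz (c(120, 240)).
#' @param threshold_sd Detection threshold in envelope SDs (5).
#' @param min_spacing Minimum event separation in seconds (0.5).
#' @param baseline `"record"` or `"episodes"`: where the envelope mean/SD
#'   are measured.
#' @return Tibble of class `swr_events` with `peak_time` (s),
#'   `peak_amp_sd` (envelope amplitude in SD units above the mean),
#'   `channel_id`; events are at least `min_spacing` apart.
#' @export
detect_swr <- function(x, episodes = NULL, band = c(120, 240),
                       threshold_sd = 5, min_spacing = 0.5,
                       baseline = c("record", "episodes")) {
  stopifnot(inherits(x, "lfp"))
  baseline <- match.arg(baseline)
  env <- band_envelope(x, band)
  amp <- env$amplitude
  times <- env$time
  base_idx <- if (baseline == "episodes" && !is.null(episodes)) {
    which(in_intervals(times, episodes$intervals))
  } else seq_along(amp)
  mu <- mean(amp[base_idx])
  sigma <- stats::sd(amp[base_idx])
  empty <- tibble(peak_time = numeric(), peak_amp_sd = numeric(),
                  channel_id = character())
  class(empty) <- c("swr_events", class(empty))
  # degenerate (near-constant) signal: envelope variation at numerical
  # noise level relative to the input scale carries no SD threshold
  input_rms <- sqrt(mean(x$samples^2))
  if (!is.finite(sigma) || sigma <= 1e-9 * max(input_rms, .Machine$double.eps)) {
    return(empty)
  }
  thr <- mu + threshold_sd * sigma
  n <- length(amp)
  is_peak <- c(FALSE, amp[2:(n - 1)] > amp[1:(n - 2)] &
                 amp[2:(n - 1)] >= amp[3:n], FALSE) & amp > thr
  cand <- which(is_peak)
  if (!is.null(episodes)) {
    cand <- cand[in_intervals(times[cand], episodes$intervals)]
  }
  if (length(cand) == 0) return(empty)
  # greedy spacing: accept by descending amplitude
  ord <- cand[order(amp[cand], decreasing = TRUE)]
  accepted <- numeric(0)
  for (i in ord) {
    if (all(abs(times[i] - accepted) >= min_spacing)) {
      accepted <- c(accepted, times[i])
    }
  }
  accepted <- sort(accepted)
  idx <- match(accepted, times)
  out <- tibble(peak_time = accepted,
                peak_amp_sd = (amp[idx] - mu) / sigma,
                channel_id = x$channel_id)
  class(out) <- c("swr_events", class(out))
  out
}

#' Event rates per window and per session type
#'
#' Counts events in consecutive non-overlapping windows (1 min) per
#' session and converts to events per minute; summaries pool windows by
#' session type.
#'
#' @param events_by_session Named list of `swr_events` tibbles (one per
#'   session), or a single tibble.
#' @param session_info Tibble with `session`, `type`, `duration` (s); for a
#'   single-events input, a single row.
#' @param window Window length in seconds (60).
#' @return List with `windows` (session, type, window, t_start,
#'   rate_per_min) and `by_type` (type, mean_rate, n_windows).
#' @export
event_rates <- function(events_by_session, session_info, window = 60) {
  if (is.data.frame(events_by_session)) {
    events_by_session <- list(events_by_session)
    names(events_by_session) <- session_info$session[1]
  }
  rows <- vector("list", length(events_by_session))
  for (i in seq_along(events_by_session)) {
    label <- names(events_by_session)[i]
    info <- session_info[session_info$session == label, ]
    wins <- window_segments(c(0, info$duration), window)
    ev <- events_by_session[[i]]
    in_range <- ev$peak_time >= 0 & ev$peak_time < max(wins$t_end)
    cnt <- tabulate(findInterval(ev$peak_time[in_range], wins$t_start),
                    nbins = nrow(wins))
    rpm <- cnt / (window / 60)
    rows[[i]] <- tibble(session = label, type = info$type,
                        window = wins$window, t_start = wins$t_start,
                        rate_per_min = rpm)
  }
  windows <- bind_rows(rows)
  by_type <- windows |>
    group_by(.data$type) |>
    summarise(mean_rate = mean(.data$rate_per_min),
              n_windows = dplyr::n(), .groups = "drop")
  list(windows = windows, by_type = by_type)
}

#' Ripple-band peak in a PSD batch
#'
#' Checks whether the mean (and SD) power spectral density across a window
#' selection has a local peak in the ripple band, judged against a
#' log-linear background: log10 PSD is regressed on log10 frequency over
#' the surrounding range excluding the band, and a peak is reported when
#' the maximum in-band residual exceeds `min_excess` log10 units and is an
#' interior local maximum of the residual curve.
#'
#' @param psd_tbl [psd_windows()] output, filtered to the window selection
#'   of interest (all-speed, low-speed, low-theta, ...).
#' @param band Ripple band in Hz (c(120, 240)).
#' @param fit_range Frequency range for the background fit.
#' @param min_excess Minimum log10 excess over the background (0.1, i.e.
#'   ~26%).
#' @param min_windows Selections with fewer windows are flagged
#'   underpowered.
#' @return List with `spectrum` (freq, mean, sd, residual), `peak_present`,
#'   `peak_freq`, `excess_log10`, `n_windows`, `underpowered`.
#' @export
swr_spectral_signature <- function(psd_tbl, band = c(120, 240),
                                   fit_range = c(60, 300), min_excess = 0.1,
                                   min_windows = 10) {
  n_windows <- length(unique(psd_tbl$window))
  spec <- psd_tbl |>
    group_by(.data$freq) |>
    summarise(mean = mean(.data$psd), sd = stats::sd(.data$psd),
              .groups = "drop") |>
    filter(.data$freq > 0)
  in_fit <- spec$freq >= fit_range[1] & spec$freq <= fit_range[2] &
    !(spec$freq >= band[1] - 10 & spec$freq <= band[2] + 10) &
    spec$mean > 0
  fit <- lm(log10(mean) ~ log10(freq), data = spec[in_fit, ])
  pred <- coef(fit)[1] + coef(fit)[2] * log10(spec$freq)
  spec$residual <- log10(pmax(spec$mean, .Machine$double.xmin)) - pred
  in_band <- which(spec$freq >= band[1] & spec$freq <= band[2])
  res <- spec$residual[in_band]
  i_max <- in_band[which.max(res)]
  interior <- i_max > min(in_band) & i_max < max(in_band)
  excess <- max(res)
  list(spectrum = spec,
       peak_present = interior && excess > min_excess,
       peak_freq = spec$freq[i_max],
       excess_log10 = excess,
       n_windows = n_windows,
       underpowered = n_windows < min_windows)
}
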