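#' Per-window power spectral density
#'
#' Splits an LFP trace into consecutive non-overlapping windows (2 s by
#' default, giving 0.5 Hz resolution at 2 kHz) and computes the one-sided
#' periodogram of each: `|FFT|^2 / (N fs)`, interior frequencies doubled,
#' so that `sum(psd) * df` equals the window's mean squared amplitude
#' (Parseval). A trailing partial window is dropped. Optionally attaches
#' the per-window mean of a speed series for selector-based averaging.
#'
#' @param x An [lfp_signal()].
#' @param window Window length in seconds (2).
#' @param speed Optional speed series (`time`, `speed`) to average per
#'   window.
#' @return Tibble with `window`, `t_start`, `freq` (Hz), `psd` (uV^2/Hz)
#'   and `mean_speed` when `speed` is given.
#' @export
psd_windows <- function(x, window = 2, speed = NULL) {
  stopifnot(inherits(x, "lfp"))
  nw <- round(window * x$rate)
  n_win <- floor(length(x$samples) / nw)
  if (n_win < 1) return(tibble(window = integer(), t_start = numeric(),
                               freq = numeric(), psd = numeric()))
  nf <- nw %/% 2 + 1
  freq <- (seq_len(nf) - 1) * x$rate / nw
  mats <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    seg <- x$samples[((w - 1) * nw + 1):(w * nw)]
    P <- Mod(fft(seg))^2 / (nw * x$rate)
    ps <- P[seq_len(nf)]
    if (nw %% 2 == 0) ps[2:(nf - 1)] <- 2 * ps[2:(nf - 1)]
    else ps[2:nf] <- 2 * ps[2:nf]
    mats[[w]] <- ps
  }
  win_id <- rep(seq_len(n_win), each = nf)
  win_t0 <- x$t0 + rep((seq_len(n_win) - 1) * window, each = nf)
  out <- tibble(window = win_id, t_start = win_t0,
                freq = rep(freq, n_win), psd = unlist(mats))
  if (!is.null(speed)) {
    wins <- window_segments(c(x$t0, x$t0 + n_win * window), window,
                            series = tibble(time = speed$time,
                                            value = speed$speed))
    out <- left_join(out, tibble(window = wins$window,
                                 mean_speed = wins$mean_value),
                     by = "window")
  }
  out
}

#' Summarize a PSD batch across windows
#'
#' @param psd_tbl Output of [psd_windows()], possibly filtered to a window
#'   selection (by speed, session, or low-theta state).
#' @return Tibble `freq`, `median`, `mean`, `sd`, `n_windows`.
#' @export
summarize_psd <- function(psd_tbl) {
  psd_tbl |>
    group_by(.data$freq) |>
    summarise(median = median(.data$psd), mean = mean(.data$psd),
              sd = stats::sd(.data$psd), n_windows = dplyr::n(),
              .groups = "drop")
}

#' Complex Morlet wavelet amplitude (and phase) of an LFP trace
#'
#' FFT-based continuous wavelet transform with an analytic Morlet wavelet
#' of fixed nondimensional width (`n_cycles`, default 6). The transform is
#' normalized so that a pure sinusoid of amplitude A at a grid frequency
#' yields instantaneous amplitude A at that frequency. Output can be
#' subsampled to a coarser clock (`out_times`) to keep dense frequency
#' grids over long sessions in memory.
#'
#' @param x An [lfp_signal()].
#' @param freqs Frequency grid in Hz (all below Nyquist).
#' @param n_cycles Wavelet width in cycles (6).
#' @param out_times Optional times (s) at which to keep the transform;
#'   defaults to the full LFP clock.
#' @param keep_phase Also return the phase matrix.
#' @return Object of class `spectral_frame`: list with `freqs`, `times`,
#'   `amplitude` (matrix, frequency x time) and optionally `phase`.
#' @export
morlet_transform <- function(x, freqs, n_cycles = 6, out_times = NULL,
                             keep_phase = FALSE) {
  stopifnot(inherits(x, "lfp"))
  if (length(freqs) == 0) {
    abort("Frequency grid is empty.", class = "degumap_parameter_error")
  }
  if (max(freqs) >= x$rate / 2) {
    abort("Frequencies must lie below Nyquist.",
          class = "degumap_parameter_error")
  }
  n <- length(x$samples)
  times <- lfp_times(x)
  out_idx <- if (is.null(out_times)) seq_len(n)
  else pmin(pmax(round((out_times - x$t0) * x$rate) + 1, 1), n)
  X <- fft(x$samples)
  w <- 2 * pi * fft_freqs(n, x$rate)
  amp <- matrix(NA_real_, length(freqs), length(out_idx))
  ph <- if (keep_phase) matrix(NA_real_, length(freqs), length(out_idx))
  for (i in seq_along(freqs)) {
    f0 <- freqs[i]
    sigma_t <- n_cycles / (2 * pi * f0)
    H <- numeric(n)
    pos <- w > 0
    H[pos] <- 2 * exp(-0.5 * sigma_t^2 * (w[pos] - 2 * pi * f0)^2)
    W <- fft(X * H, inverse = TRUE) / n
    amp[i, ] <- Mod(W[out_idx])
    if (keep_phase) ph[i, ] <- Arg(W[out_idx])
  }
  structure(list(freqs = freqs, times = times[out_idx], amplitude = amp,
                 phase = ph, n_cycles = n_cycles),
            class = "spectral_frame")
}

#' @export
print.spectral_frame <- function(x, ...) {
  cat(sprintf("<spectral_frame> %d frequencies (%.3g-%.3g Hz) x %d times\n",
              length(x$freqs), min(x$freqs), max(x$freqs), length(x$times)))
  invisible(x)
}

#' @export
tidy.spectral_frame <- function(x, ...) {
  out <- tibble(
    freq = rep(x$freqs, times = length(x$times)),
    time = rep(x$times, each = length(x$freqs)),
    amplitude = as.vector(x$amplitude)
  )
  if (!is.null(x$phase)) out$phase <- as.vector(x$phase)
  out
}

#' Instantaneous amplitude and phase of a frequency band
#'
#' Band-passes the LFP with a zero-phase 4th-order Butterworth response
#' (applied spectrally, i.e. the exact forward-backward magnitude response,
#' stable for arbitrarily narrow bands) and takes the analytic signal in
#' the same pass, yielding the instantaneous amplitude and phase of the
#' whole band. Phase 0 corresponds to the positive peak of the
#' band-filtered signal and increases with time.
#'
#' @param x An [lfp_signal()].
#' @param band Length-2 numeric `c(low, high)` in Hz, below Nyquist.
#' @param order Butterworth order (4).
#' @return Tibble with `time`, `filtered`, `amplitude`, `phase`
#'   (radians in (-pi, pi]).
#' @export
band_envelope <- function(x, band, order = 4) {
  stopifnot(inherits(x, "lfp"))
  if (!(band[1] > 0 && band[2] > band[1] && band[2] < x$rate / 2)) {
    abort("Band must satisfy 0 < low < high < Nyquist.",
          class = "degumap_parameter_error")
  }
  n <- length(x$samples)
  f <- fft_freqs(n, x$rate)
  gain <- butter_bandpass_gain(abs(f), band[1], band[2], order)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  A <- fft(fft(x$samples) * gain * h, inverse = TRUE) / n
  tibble(time = lfp_times(x), filtered = Re(A), amplitude = Mod(A),
         phase = Arg(A))
}

#' Percent change of amplitude with running speed
#'
#' For each frequency (or band), the mean instantaneous amplitude per speed
#' bin, expressed as percent change relative to the amplitude in the lowest
#' (reference, 0 cm/s) bin — the profile whose sign structure defines the
#' frequency bands.
#'
#' @param amplitude Either a `spectral_frame` (wavelet amplitudes) or a
#'   tibble with columns `time`, `amplitude` and a `band` label column
#'   (Hilbert band envelopes).
#' @param speed Speed series (`time`, `speed`); interpolated onto the
#'   amplitude clock.
#' @param speed_bins Bin edges in cm/s (default 0 to 30 by 2.5).
#' @return Tibble of class `speed_profile` with `freq` (or `band`),
#'   `speed_bin` (lower edge), `speed_mid`, `mean_amplitude`, `pct_change`,
#'   `n` samples.
#' @export
speed_amplitude_profile <- function(amplitude, speed,
                                    speed_bins = seq(0, 30, by = 2.5)) {
  profile_one <- function(times, amps, label_col, label) {
    v <- approx(speed$time, speed$speed, xout = times, rule = 2)$y
    keep <- !is.na(v) & v >= speed_bins[1] & v < max(speed_bins)
    bin <- findInterval(v[keep], speed_bins, rightmost.closed = FALSE)
    a <- amps[keep]
    mean_amp <- tapply(a, factor(bin, levels = seq_len(length(speed_bins) - 1)),
                       mean)
    nn <- tapply(rep(1, length(bin)),
                 factor(bin, levels = seq_len(length(speed_bins) - 1)), sum)
    if (is.na(mean_amp[1])) {
      abort("Reference (lowest) speed bin is empty; no baseline amplitude.",
            class = "degumap_parameter_error")
    }
    out <- tibble(
      speed_bin = speed_bins[-length(speed_bins)],
      speed_mid = speed_bins[-length(speed_bins)] + diff(speed_bins) / 2,
      mean_amplitude = as.numeric(mean_amp),
      pct_change = 100 * (as.numeric(mean_amp) / mean_amp[[1]] - 1),
      n = ifelse(is.na(nn), 0L, as.integer(nn))
    )
    out[[label_col]] <- label
    out
  }
  if (inherits(amplitude, "spectral_frame")) {
    rows <- lapply(seq_along(amplitude$freqs), function(i) {
      profile_one(amplitude$times, amplitude$amplitude[i, ], "freq",
                  amplitude$freqs[i])
    })
    out <- bind_rows(rows)
    out <- out[c("freq", setdiff(names(out), "freq"))]
  } else {
    amplitude <- as_tibble(amplitude)
    rows <- lapply(split(amplitude, amplitude$band), function(d) {
      profile_one(d$time, d$amplitude, "band", d$band[1])
    })
    out <- bind_rows(rows)
    out <- out[c("band", setdiff(names(out), "band"))]
  }
  class(out) <- c("speed_profile", class(out))
  out
}

#' Hilbert band amplitude versus speed, with a running-modulation test
#'
#' Per-band version of [speed_amplitude_profile()] using the Hilbert
#' envelope of the band-passed LFP, plus a Wilcoxon signed-rank test of the
#' percent changes over the 10-30 cm/s range against zero.
#'
#' @param x An [lfp_signal()].
#' @param speed Speed series.
#' @param bands Band table (`band`, `low`, `high`); default the four
#'   speed-defined canonical bands.
#' @param speed_bins Bin edges in cm/s.
#' @param test_range Speed range (cm/s) over which to test modulation.
#' @return List with `profile` (a `speed_profile` tibble) and `tests`
#'   (tibble `band`, `median_pct`, `p_value`).
#' @export
band_speed_profile <- function(x, speed, bands = canonical_bands()[1:4, ],
                               speed_bins = seq(0, 30, by = 2.5),
                               test_range = c(10, 30)) {
  env <- purrr::map(seq_len(nrow(bands)), function(i) {
    e <- band_envelope(x, c(bands$low[i], bands$high[i]))
    tibble(time = e$time, amplitude = e$amplitude, band = bands$band[i])
  })
  profile <- speed_amplitude_profile(bind_rows(env), speed, speed_bins)
  tests <- profile |>
    filter(.data$speed_bin >= test_range[1], .data$speed_bin < test_range[2]) |>
    group_by(.data$band) |>
    summarise(median_pct = median(.data$pct_change),
              p_value = wilcox.test(.data$pct_change, exact = FALSE)$p.value,
              .groups = "drop")
  list(profile = profile, tests = tests)
}

#' Derive frequency-band boundaries from a speed-amplitude profile
#'
#' Frequency bands are contiguous regimes of consistent amplitude-speed
#' coupling sign: for each frequency the mean percent change over a
#' high-speed range is computed; frequencies with |change| below
#' `min_effect` are treated as uncoupled; runs of identical sign (merging
#' across sub-threshold stretches that separate same-sign runs) become
#' regimes; and the boundary between adjacent opposite-sign regimes is
#' placed at the interpolated zero crossing of the coupling curve — where
#' the relationship between amplitude and running speed changes sign. The
#' outer edges of the first and last regime are their outermost coupled
#' grid frequencies. The canonical band constants are available from
#' [canonical_bands()].
#'
#' @param profile A `speed_profile` over a dense frequency grid (from
#'   [speed_amplitude_profile()] on a `spectral_frame`).
#' @param high_range Speed range (cm/s) at which to read the coupling sign.
#' @param min_effect Minimum |percent change| for a frequency to count as
#'   coupled (default 3).
#' @return Tibble with `low`, `high` (Hz; interior boundaries are
#'   interpolated crossings, not grid points), `coupling` (+1/-1),
#'   `max_pct` (largest-|.| percent change in the regime); zero rows when
#'   no frequency is coupled.
#' @export
derive_band_boundaries <- function(profile, high_range = c(10, 30),
                                   min_effect = 3) {
  per_freq <- profile |>
    filter(.data$speed_bin >= high_range[1],
           .data$speed_bin < high_range[2]) |>
    group_by(.data$freq) |>
    summarise(change = mean(.data$pct_change), .groups = "drop") |>
    arrange(.data$freq)
  f <- per_freq$freq
  ch <- per_freq$change
  s <- sign(ch) * (abs(ch) >= min_effect)
  runs <- rle(s)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values != 0)
  if (length(keep) == 0) {
    return(tibble(low = numeric(), high = numeric(), coupling = numeric(),
                  max_pct = numeric()))
  }
  # merge same-sign runs separated only by sub-threshold stretches
  regimes <- list()
  for (i in keep) {
    if (length(regimes) > 0 &&
        regimes[[length(regimes)]]$sign == runs$values[i]) {
      regimes[[length(regimes)]]$to <- ends[i]
    } else {
      regimes[[length(regimes) + 1]] <- list(sign = runs$values[i],
                                             from = starts[i], to = ends[i])
    }
  }
  nr <- length(regimes)
  low <- numeric(nr); high <- numeric(nr)
  max_pct <- numeric(nr); coupling <- numeric(nr)
  for (i in seq_len(nr)) {
    coupling[i] <- regimes[[i]]$sign
    seg <- ch[regimes[[i]]$from:regimes[[i]]$to]
    max_pct[i] <- seg[which.max(abs(seg))]
    low[i] <- f[regimes[[i]]$from]
    high[i] <- f[regimes[[i]]$to]
  }
  for (i in seq_len(nr - 1)) {
    if (regimes[[i]]$sign != regimes[[i + 1]]$sign) {
      # zero crossing of the coupling curve between the two regimes
      a <- regimes[[i]]$to
      b <- regimes[[i + 1]]$from
      idx <- a:(b - 1)
      cross <- idx[sign(ch[idx]) != sign(ch[idx + 1]) & sign(ch[idx]) != 0]
      j <- if (length(cross) > 0) cross[1] else a
      x0 <- f[j] + (0 - ch[j]) / (ch[j + 1] - ch[j]) * (f[j + 1] - f[j])
      high[i] <- x0
      low[i + 1] <- x0
    }
  }
  tibble(low = low, high = high, coupling = coupling, max_pct = max_pct)
}
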