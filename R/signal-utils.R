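#' Construct an LFP signal object
#'
#' A light container for a single-channel local field potential trace:
#' a numeric sample vector with its sampling rate, start time, and channel
#' labels. Samples are in microvolts.
#'
#' @param samples Numeric vector of samples (uV); must be finite.
#' @param rate Sampling rate in Hz.
#' @param t0 Time of the first sample in seconds (session clock).
#' @param channel_id,tetrode_id Optional labels.
#' @return An object of class `lfp`.
#' @export
lfp_signal <- function(samples, rate, t0 = 0, channel_id = "ch1",
                       tetrode_id = NA_character_) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) abort("LFP samples must be finite.")
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    abort("`rate` must be a single positive number (Hz).")
  }
  structure(
    list(samples = samples, rate = rate, t0 = t0,
         channel_id = channel_id, tetrode_id = tetrode_id),
    class = "lfp"
  )
}

#' @export
print.lfp <- function(x, ...) {
  cat(sprintf("<lfp> channel %s: %d samples @ %g Hz (%.1f s)\n",
              x$channel_id, length(x$samples), x$rate,
              length(x$samples) / x$rate))
  invisible(x)
}

#' @export
as_tibble.lfp <- function(x, ...) {
  tibble::tibble(
    time = lfp_times(x),
    value = x$samples,
    channel_id = x$channel_id
  )
}

lfp_times <- function(x) {
  x$t0 + (seq_along(x$samples) - 1) / x$rate
}

lfp_duration <- function(x) length(x$samples) / x$rate

#' Analytic signal via the Fourier transform
#'
#' Returns the complex analytic signal of a real vector (negative
#' frequencies zeroed, positive doubled), whose modulus is the instantaneous
#' amplitude and whose argument the instantaneous phase.
#'
#' @param x Numeric vector.
#' @return Complex vector of the same length.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Zero-phase magnitude response of an order-n Butterworth band-pass,
# i.e. |H(f)|^2, the gain a forward-backward (filtfilt) application of the
# filter imposes. Closed form, evaluated on a frequency grid: numerically
# exact for arbitrarily narrow normalized bands where the time-domain IIR
# recursion loses stability.
butter_bandpass_gain <- function(f, low, high, order = 4) {
  f0sq <- low * high
  bw <- high - low
  g <- numeric(length(f))
  pos <- f > 0
  u <- (f[pos]^2 - f0sq) / (bw * f[pos])
  g[pos] <- 1 / (1 + u^(2 * order))
  # odd exponents impossible (2*order even), u^even >= 0, gain in (0, 1]
  g
}

butter_lowpass_gain <- function(f, cutoff, order = 4) {
  1 / (1 + (f / cutoff)^(2 * order))
}

# FFT frequency axis in Hz (positive then negative), length n at rate fs
fft_freqs <- function(n, fs) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  k * fs / n
}

# Centered moving average with reflection padding at the edges; O(n) via
# cumulative sums.
moving_average <- function(x, k) {
  k <- as.integer(k)
  if (k <= 1) return(x)
  n <- length(x)
  half <- k %/% 2
  pad <- c(x[half:1], x, x[n:(n - half + 1)])
  cs <- cumsum(pad)
  w <- 2 * half + 1
  out <- (cs[(w):(n + w - 1)] - c(0, cs[1:(n - 1)])) / w
  out
}

# 1/f ("pink") background noise, scaled to a target standard deviation.
pink_noise <- function(n, sd = 1) {
  if (sd <= 0 || n < 2) return(numeric(n))
  white <- rnorm(n)
  X <- fft(white)
  f <- abs(fft_freqs(n, 1))
  scale <- ifelse(f > 0, 1 / sqrt(f), 0)
  x <- Re(fft(X * scale, inverse = TRUE) / n)
  x * sd / stats::sd(x)
}
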