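#' Simulate a foraging trajectory
#'
#' Ornstein-Uhlenbeck velocity process in two dimensions, integrated at the
#' tracking rate and reflected at the arena walls, interleaved with
#' immobility bouts: foraging rodents alternate movement with pauses, and
#' the pauses are what populate the 0 cm/s reference bin of
#' speed-amplitude profiles. Bout durations are exponential with means
#' `move_bout_s` and `pause_bout_s`; during pauses the velocity is zero.
#' The OU sd is scaled by the movement duty cycle so the long-run mean
#' speed (pauses included) matches `mean_speed`: the stationary speed of
#' the OU component is Rayleigh with mean `sigma * sqrt(pi/2)`.
#'
#' @param duration Session length in seconds.
#' @param arena_side Arena side in cm.
#' @param mean_speed Target long-run mean speed in cm/s (0 gives a
#'   stationary animal at the arena center).
#' @param persistence Velocity autocorrelation time constant in seconds.
#' @param rate Tracking rate in Hz.
#' @param move_bout_s,pause_bout_s Mean movement / pause bout lengths in
#'   seconds; `pause_bout_s = 0` disables pausing.
#' @param seed Optional integer seed.
#' @return A [as_trajectory()] tibble.
#' @export
simulate_trajectory <- function(duration, arena_side = 90, mean_speed = 15,
                                persistence = 2, rate = 50,
                                move_bout_s = 8, pause_bout_s = 2,
                                seed = NULL) {
  if (duration <= 0 || arena_side <= 0 || mean_speed < 0 || persistence <= 0) {
    abort("`duration`, `arena_side`, `persistence` must be positive and `mean_speed` non-negative.",
          class = "degumap_parameter_error")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- floor(duration * rate)
  dt <- 1 / rate
  times <- (seq_len(n) - 1) * dt
  if (mean_speed == 0) {
    return(as_trajectory(tibble(time = times, x = arena_side / 2,
                                y = arena_side / 2), arena_side))
  }
  moving <- rep(TRUE, n)
  duty <- 1
  if (pause_bout_s > 0) {
    duty <- move_bout_s / (move_bout_s + pause_bout_s)
    i <- 1L
    state <- TRUE
    while (i <= n) {
      len <- max(1L, round(stats::rexp(1, 1 / if (state) move_bout_s
                                       else pause_bout_s) * rate))
      moving[i:min(n, i + len - 1L)] <- state
      i <- i + len
      state <- !state
    }
  }
  sigma <- (mean_speed / duty) / sqrt(pi / 2)
  a <- exp(-dt / persistence)
  b <- sigma * sqrt(1 - a^2)
  ex <- rnorm(n) * b
  ey <- rnorm(n) * b
  x <- numeric(n); y <- numeric(n)
  vx <- rnorm(1) * sigma; vy <- rnorm(1) * sigma
  px <- runif(1, 0.25, 0.75) * arena_side
  py <- runif(1, 0.25, 0.75) * arena_side
  for (i in seq_len(n)) {
    vx <- a * vx + ex[i]
    vy <- a * vy + ey[i]
    if (moving[i]) {
      px <- px + vx * dt
      py <- py + vy * dt
      if (px < 0) { px <- -px; vx <- -vx }
      if (px > arena_side) { px <- 2 * arena_side - px; vx <- -vx }
      if (py < 0) { py <- -py; vy <- -vy }
      if (py > arena_side) { py <- 2 * arena_side - py; vy <- -vy }
    }
    x[i] <- px; y[i] <- py
  }
  as_trajectory(tibble(time = times, x = x, y = y), arena_side)
}

#' Simulate a place cell as an inhomogeneous Poisson process
#'
#' Firing intensity is a 2D Gaussian bump over the arena,
#' `lambda(x, y) = baseline + (peak - baseline) * exp(-d^2 / (2 width^2))`
#' with `d` the distance to the field center, evaluated along the
#' trajectory. Spikes are drawn per tracking interval (Poisson counts,
#' uniform placement within the interval).
#'
#' @param traj A trajectory tibble.
#' @param center Length-2 field center (cm).
#' @param width Gaussian field sd in cm.
#' @param peak_rate,baseline_rate Firing rate at the center / far away (Hz).
#' @param seed Optional integer seed.
#' @return Sorted numeric vector of spike times (s).
#' @export
simulate_place_cell <- function(traj, center, width = 10, peak_rate = 10,
                                baseline_rate = 0.1, seed = NULL) {
  if (width <= 0 || peak_rate < baseline_rate || baseline_rate < 0) {
    abort("Need width > 0 and peak_rate >= baseline_rate >= 0.",
          class = "degumap_parameter_error")
  }
  if (!is.null(seed)) set.seed(seed)
  d2 <- (traj$x - center[1])^2 + (traj$y - center[2])^2
  lambda <- baseline_rate + (peak_rate - baseline_rate) *
    exp(-d2 / (2 * width^2))
  dt <- trajectory_dwell(traj)
  counts <- rpois(length(lambda), lambda * dt)
  idx <- rep.int(seq_along(counts), counts)
  if (length(idx) == 0) return(numeric(0))
  sort(traj$time[idx] + runif(length(idx)) * dt[idx])
}

#' Default speed-coupled LFP component table
#'
#' One broadband component per speed-coupling regime of the CA1 LFP, with
#' amplitude slopes set to reproduce the characteristic magnitudes: delta
#' decreasing by ~28% between immobility and 30 cm/s running, theta
#' increasing by ~16%, the broad 12-30 Hz beta regime decreasing by ~12%,
#' gamma increasing by ~20%. The component supports tile the spectrum
#' contiguously (real LFP has no silent bands between regimes; note the
#' generative beta regime spans 12-30 Hz even though the conservative
#' analysis band in [canonical_bands()] starts at 20 Hz to stay clear of
#' the first theta harmonic).
#'
#' `carrier_freq = NA` makes a component band-limited 1/f-shaped noise
#' spanning the band; the default RMS amplitudes are drawn from a common
#' 1/f spectral envelope so the composite spectrum is continuous across
#' band edges, as in real recordings. A finite `carrier_freq` gives a pure
#' sinusoid at that frequency instead.
#'
#' @return A tibble with columns `band`, `low`, `high`, `amplitude0` (uV,
#'   RMS for broadband / sine amplitude for carriers), `speed_slope`
#'   (fractional amplitude change per cm/s) and `carrier_freq` (Hz or NA).
#' @export
default_lfp_bands <- function() {
  low <- c(1, 6, 12, 31)
  high <- c(5, 11, 30, 100)
  tibble(
    band = c("delta", "theta", "beta", "gamma"),
    low = low,
    high = high,
    # common 1/f envelope: band RMS = sqrt(C * log(high/low)), C = 1850 uV^2
    amplitude0 = round(sqrt(1850 * log(high / low)), 1),
    speed_slope = c(-0.0093, 0.0053, -0.0040, 0.0067),
    carrier_freq = NA_real_
  )
}

# band-limited unit-RMS noise in [low, high] Hz with an in-band 1/f
# (pink) spectral shape, so adjacent bands generated from a common
# envelope join with continuous spectral density
bandlimited_noise <- function(n, fs, low, high) {
  X <- fft(rnorm(n))
  f <- abs(fft_freqs(n, fs))
  shape <- ifelse(f >= low & f <= high, 1 / sqrt(pmax(f, low)), 0)
  x <- Re(fft(X * shape, inverse = TRUE) / n)
  s <- stats::sd(x)
  if (s == 0) numeric(n) else x / s
}

#' Simulate an LFP trace with speed-coupled bands and injected ripples
#'
#' The trace is a sum of per-band components whose instantaneous amplitude
#' is `amplitude0 * (1 + speed_slope * v(t))` (clamped at zero with a
#' warning if the slope drives it negative), a 1/f pink-noise background,
#' and optional sharp-wave-ripple transients: Hanning-windowed bursts at a
#' ripple-band frequency riding on a slow negative deflection emulating the
#' sharp wave.
#'
#' @param duration Seconds.
#' @param speed Optional speed series (tibble `time`, `speed`); linearly
#'   interpolated onto the LFP clock; NULL means immobile (v = 0).
#' @param bands Component table as in [default_lfp_bands()].
#' @param noise_sd Pink-noise background SD in uV.
#' @param ripples Optional tibble/list with `event_times` (s, burst
#'   centers = envelope peaks), and scalars
#'   `ripple_freq` (Hz in 120-240), `duration` (s), `envelope_amp` (uV),
#'   `sharp_wave_amp` (uV, optional).
#' @param rate Sampling rate in Hz (2000).
#' @param seed Optional integer seed.
#' @return An [lfp_signal()].
#' @export
simulate_lfp <- function(duration, speed = NULL, bands = default_lfp_bands(),
                         noise_sd = 15, ripples = NULL, rate = 2000,
                         seed = NULL) {
  if (nrow(bands) == 0) {
    abort("`bands` must be non-empty.", class = "degumap_parameter_error")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- floor(duration * rate)
  t <- (seq_len(n) - 1) / rate
  v <- if (is.null(speed)) {
    numeric(n)
  } else {
    approx(speed$time, speed$speed, xout = t, rule = 2)$y
  }
  v[is.na(v)] <- 0
  x <- numeric(n)
  clamped <- FALSE
  for (i in seq_len(nrow(bands))) {
    gain <- 1 + bands$speed_slope[i] * v
    if (any(gain < 0)) { gain <- pmax(gain, 0); clamped <- TRUE }
    comp <- if (is.na(bands$carrier_freq[i])) {
      bandlimited_noise(n, rate, bands$low[i], bands$high[i])
    } else {
      sin(2 * pi * bands$carrier_freq[i] * t + runif(1, 0, 2 * pi))
    }
    x <- x + bands$amplitude0[i] * gain * comp
  }
  if (clamped) warn("Speed slope drove a band amplitude negative; clamped at 0.")
  if (noise_sd > 0) x <- x + pink_noise(n, noise_sd)
  if (!is.null(ripples)) {
    rf <- ripples$ripple_freq %||% 180
    rd <- ripples$duration %||% 0.08
    ra <- ripples$envelope_amp %||% 100
    swa <- ripples$sharp_wave_amp %||% ra
    ev <- ripples$event_times
    if (any(diff(sort(ev)) <= 0.5)) {
      warn("Injected ripple events closer than 0.5 s.")
    }
    for (e in ev) {
      # event time marks the burst center (the envelope peak)
      i0 <- round((e - rd / 2) * rate) + 1
      m <- round(rd * rate)
      idx <- i0:(i0 + m - 1)
      keep <- idx >= 1 & idx <= n
      hann <- 0.5 * (1 - cos(2 * pi * (seq_len(m) - 1) / (m - 1)))
      burst <- ra * hann * sin(2 * pi * rf * (seq_len(m) - 1) / rate)
      x[idx[keep]] <- x[idx[keep]] + burst[keep]
      # slow negative sharp-wave deflection under the burst
      sw_sd <- rd / 2
      tt <- (idx - i0 - m / 2) / rate
      x[idx[keep]] <- x[idx[keep]] - swa * exp(-tt[keep]^2 / (2 * sw_sd^2))
    }
  }
  lfp_signal(x, rate)
}

#' Simulate spikes phase-locked to an LFP band
#'
#' Spiking intensity follows a von Mises modulation of the band's
#' instantaneous Hilbert phase:
#' `lambda(t) = mean_rate * exp(kappa * cos(phi(t) - mu)) / <exp(kappa cos)>`,
#' normalized so the session-average rate equals `mean_rate`. As the spike
#' count grows, the mean vector length of the spike phases approaches the
#' Bessel ratio `I1(kappa)/I0(kappa)`.
#'
#' @param lfp An [lfp_signal()].
#' @param band Length-2 numeric band `c(low, high)` in Hz.
#' @param kappa von Mises concentration (>= 0).
#' @param preferred_phase Preferred phase mu in radians.
#' @param mean_rate Session-mean firing rate in Hz.
#' @param seed Optional integer seed.
#' @return Sorted numeric vector of spike times (s).
#' @export
simulate_phase_locked_spikes <- function(lfp, band = c(6, 11), kappa = 2,
                                         preferred_phase = 0, mean_rate = 2,
                                         seed = NULL) {
  if (kappa < 0) abort("`kappa` must be non-negative.",
                       class = "degumap_parameter_error")
  if (band[2] >= lfp$rate / 2) {
    abort("Band must lie below the Nyquist frequency.",
          class = "degumap_parameter_error")
  }
  if (!is.null(seed)) set.seed(seed)
  env <- band_envelope(lfp, band)
  g <- exp(kappa * cos(env$phase - preferred_phase))
  lambda <- mean_rate * g / mean(g)
  dt <- 1 / lfp$rate
  counts <- rpois(length(lambda), lambda * dt)
  idx <- rep.int(seq_along(counts), counts)
  if (length(idx) == 0) return(numeric(0))
  sort(lfp$t0 + (idx - 1) * dt + runif(length(idx)) * dt)
}

#' Draw von Mises circular samples
#'
#' Best-Fisher rejection sampler; `kappa = 0` gives uniform angles.
#'
#' @param n Number of samples.
#' @param mu Mean direction (radians).
#' @param kappa Concentration (>= 0).
#' @return Angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) abort("`kappa` must be non-negative.",
                       class = "degumap_parameter_error")
  if (kappa == 0) return(wrap_angle(runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    f <- f[ok]; u3 <- u3[ok]
    k <- length(f)
    if (k > 0) {
      theta <- sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1))
      out[(got + 1):(got + k)] <- theta
      got <- got + k
    }
  }
  wrap_angle(out + mu)
}

wrap_angle <- function(x) {
  out <- (x + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

#' Generate a complete synthetic session
#'
#' Convenience wrapper assembling a [session_record()] with a foraging
#' trajectory, place cells and/or homogeneous Poisson units, and a
#' speed-coupled LFP channel with optional injected ripples.
#'
#' @param duration Seconds.
#' @param session_type Session type string.
#' @param place_cells Tibble with columns `unit_id`, `cx`, `cy`, `width`,
#'   `peak`, `baseline`, or NULL.
#' @param poisson_units Tibble with columns `unit_id`, `rate`, or NULL.
#' @param lfp_bands Component table for [simulate_lfp()]; NULL skips LFP.
#' @param noise_sd Pink-noise SD (uV).
#' @param ripples Ripple injection spec (see [simulate_lfp()]).
#' @param objects Object layout tibble (`label`, `x`, `y`) or NULL.
#' @param arena_side,mean_speed,seed Passed through to the generators.
#' @return A [session_record()] with a `ground_truth` attribute.
#' @export
simulate_session <- function(duration = 600, session_type = "open_field",
                             place_cells = NULL, poisson_units = NULL,
                             lfp_bands = default_lfp_bands(), noise_sd = 15,
                             ripples = NULL, objects = NULL, arena_side = 90,
                             mean_speed = 15, seed = 1) {
  set.seed(seed)
  traj <- simulate_trajectory(duration, arena_side, mean_speed)
  spikes <- tibble(unit_id = character(), time = numeric())
  if (!is.null(place_cells)) {
    for (i in seq_len(nrow(place_cells))) {
      ts <- simulate_place_cell(traj,
                                center = c(place_cells$cx[i], place_cells$cy[i]),
                                width = place_cells$width[i],
                                peak_rate = place_cells$peak[i],
                                baseline_rate = place_cells$baseline[i])
      spikes <- bind_rows(spikes, tibble(unit_id = place_cells$unit_id[i],
                                         time = ts))
    }
  }
  if (!is.null(poisson_units)) {
    for (i in seq_len(nrow(poisson_units))) {
      nsp <- rpois(1, poisson_units$rate[i] * duration)
      spikes <- bind_rows(spikes,
                          tibble(unit_id = poisson_units$unit_id[i],
                                 time = sort(runif(nsp, 0, duration))))
    }
  }
  lfp <- list()
  if (!is.null(lfp_bands)) {
    speed <- compute_speed(traj)
    lfp <- list(ch1 = simulate_lfp(duration, speed = speed,
                                   bands = lfp_bands, noise_sd = noise_sd,
                                   ripples = ripples))
  }
  out <- session_record(session_type, duration, spikes = spikes,
                        trajectory = traj, lfp = lfp, objects = objects,
                        arena_side = arena_side)
  attr(out, "ground_truth") <- list(place_cells = place_cells,
                                    poisson_units = poisson_units,
                                    lfp_bands = lfp_bands, ripples = ripples,
                                    mean_speed = mean_speed, seed = seed)
  out
}
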