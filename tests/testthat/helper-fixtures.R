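# Small deterministic fixtures shared across test files.

# trajectory visiting every bin of a coarse grid with equal dwell time:
# raster scan over an arena at fixed step and rate
raster_trajectory <- function(arena_side = 15, step = 2.5, rate = 50,
                              dwell_per_point = 0.2) {
  n_bins <- arena_side / step
  centers <- (seq_len(n_bins) - 0.5) * step
  pts <- expand.grid(x = centers, y = centers)
  reps <- dwell_per_point * rate
  x <- rep(pts$x, each = reps)
  y <- rep(pts$y, each = reps)
  as_trajectory(
    tibble::tibble(time = (seq_along(x) - 1) / rate, x = x, y = y),
    arena_side = arena_side
  )
}

# straight-line constant-velocity path
line_trajectory <- function(duration = 10, speed = 20, rate = 50,
                            arena_side = 300, y0 = 150) {
  t <- seq(0, duration, by = 1 / rate)
  as_trajectory(tibble::tibble(time = t, x = pmin(speed * t, arena_side),
                               y = y0),
                arena_side = arena_side)
}

# hand-built two-bin rate map exercising the information formula directly
two_bin_map <- function(rates = c(2, 0), p = c(0.5, 0.5)) {
  visited <- matrix(c(TRUE, TRUE), 1, 2)
  rate <- matrix(rates, 1, 2)
  pm <- matrix(p, 1, 2)
  structure(
    list(rate = rate, occupancy = pm * 100, p = pm, visited = visited,
         lambda_mean = sum(pm * rate), bin_side = 2.5, arena_side = 5,
         n_spikes_used = 100L, n_spikes_dropped = 0L),
    class = "rate_map"
  )
}

# pure-tone LFP helper
tone_lfp <- function(freq, duration = 30, amp = 1, rate = 2000, phase = 0) {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  lfp_signal(amp * sin(2 * pi * freq * t + phase), rate)
}

# homogeneous Poisson spike times
poisson_spikes <- function(rate_hz, duration, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sort(runif(rpois(1, rate_hz * duration), 0, duration))
}

# block-design LFP: theta on/off in alternating 60 s blocks, optional
# injected ripples centered in the off blocks
block_lfp <- function(duration = 600, ripple_times = NULL, noise_sd = 10,
                      ripple_amp = 100, seed = 101) {
  set.seed(seed)
  rate <- 2000
  t <- seq_len(duration * rate) / rate
  theta_on <- rep(rep(c(TRUE, FALSE), each = 60 * rate),
                  length.out = duration * rate)
  base <- 40 * sin(2 * pi * 8 * t) * theta_on + 25 * sin(2 * pi * 3 * t) +
    degumap:::pink_noise(duration * rate, noise_sd)
  x <- lfp_signal(base, rate)
  if (!is.null(ripple_times)) {
    r <- simulate_lfp(duration, bands = tibble::tibble(
      band = "flat", low = 1, high = 2, amplitude0 = 0, speed_slope = 0,
      carrier_freq = NA), noise_sd = 0,
      ripples = list(event_times = ripple_times, envelope_amp = ripple_amp),
      seed = seed + 1)
    x <- lfp_signal(base + r$samples, rate)
  }
  x
}
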