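test_that("periodograms localize tones and conserve energy (Parseval)", {
  x <- tone_lfp(8, duration = 30, amp = 3)
  psd <- psd_windows(x)
  m <- summarize_psd(psd)
  expect_equal(m$freq[which.max(m$median)], 8)
  # Parseval per window: sum(psd) * df = mean square of the window
  df <- diff(sort(unique(psd$freq)))[1]
  w1 <- psd$psd[psd$window == 1]
  seg <- x$samples[1:4000]
  expect_equal(sum(w1) * df, mean(seg^2), tolerance = 0.01)
  # trailing partial window is dropped
  x2 <- lfp_signal(rnorm(5000), 2000)   # 2.5 s
  expect_equal(max(psd_windows(x2)$window), 1)
})

test_that("PSD windows carry speed selectors that separate states", {
  tr <- simulate_trajectory(300, seed = 71)
  sp <- compute_speed(tr)
  x <- simulate_lfp(300, speed = sp, seed = 72)
  psd <- psd_windows(x, speed = sp)
  expect_true("mean_speed" %in% names(psd))
  slow <- summarize_psd(dplyr::filter(psd, mean_speed < 5))
  fast <- summarize_psd(dplyr::filter(psd, mean_speed >= 5))
  # theta amplitude increases and delta decreases with running
  expect_gt(fast$median[fast$freq == 8] / slow$median[slow$freq == 8], 1)
  expect_lt(fast$median[fast$freq == 3] / slow$median[slow$freq == 3], 1)
})

test_that("Morlet transform localizes tones and recovers known envelopes", {
  x <- tone_lfp(8, duration = 30, amp = 5)
  mt <- morlet_transform(x, c(4, 8, 16))
  expect_equal(which.max(rowMeans(mt$amplitude)), 2L)
  expect_lt(abs(mean(mt$amplitude[2, 2000:58000]) - 5) / 5, 0.01)
  # amplitude-modulated tone: envelope recovered mid-record
  t <- seq(0, 30 - 5e-4, by = 5e-4)
  envl <- 1 + 0.5 * sin(2 * pi * 0.5 * t)
  am <- lfp_signal(envl * sin(2 * pi * 10 * t), 2000)
  mt2 <- morlet_transform(am, 10)
  mid <- 10000:50000
  rms_err <- sqrt(mean((mt2$amplitude[1, mid] - envl[mid])^2)) /
    sqrt(mean(envl[mid]^2))
  expect_lt(rms_err, 0.05)
  # chirp ridge increases monotonically
  chirp <- lfp_signal(sin(2 * pi * (2 * t + (48 / 60) * t^2 / 2)), 2000)
  mt3 <- morlet_transform(chirp, seq(2, 50, by = 2),
                          out_times = seq(2, 28, by = 2))
  ridge <- mt3$freqs[apply(mt3$amplitude, 2, which.max)]
  expect_true(all(diff(ridge) >= 0))
  expect_error(morlet_transform(x, numeric(0)),
               class = "degumap_parameter_error")
  expect_error(morlet_transform(x, 1500),
               class = "degumap_parameter_error")
})

test_that("band envelopes pass in-band tones and reject out-of-band tones", {
  x <- tone_lfp(8, duration = 20, amp = 2)
  e <- band_envelope(x, c(6, 11))
  core <- 4000:36000
  expect_lt(max(abs(e$amplitude[core] - 2)) / 2, 0.02)
  # out-of-band rejection, evaluated against the Butterworth gain bound
  e2 <- band_envelope(x, c(35, 100))
  expect_lt(max(e2$amplitude[core]), 0.05 * 2)
  # phase advances 2*pi per carrier cycle
  ph <- degumap:::unwrap_phase(e$phase[core])
  cycles <- (ph[length(ph)] - ph[1]) / (2 * pi)
  expect_equal(cycles, 8 * (length(core) - 1) / 2000, tolerance = 0.01)
  expect_error(band_envelope(x, c(500, 1500)),
               class = "degumap_parameter_error")
})

test_that("Morlet and Hilbert envelopes agree for a centered narrowband tone", {
  t <- seq(0, 20 - 5e-4, by = 5e-4)
  envl <- 1 + 0.3 * sin(2 * pi * 0.3 * t)
  x <- lfp_signal(envl * sin(2 * pi * 8 * t), 2000)
  hb <- band_envelope(x, c(6, 11))$amplitude
  mw <- morlet_transform(x, 8)$amplitude[1, ]
  mid <- 8000:32000
  rel <- sqrt(mean((hb[mid] - mw[mid])^2)) / sqrt(mean(hb[mid]^2))
  expect_lt(rel, 0.1)
})

test_that("speed-amplitude profiles are zero-referenced and flat without coupling", {
  tr <- simulate_trajectory(600, seed = 73)
  sp <- compute_speed(tr)
  x <- simulate_lfp(600, speed = sp, bands = tibble::tibble(
    band = "theta", low = 6, high = 11, amplitude0 = 50, speed_slope = 0,
    carrier_freq = NA), noise_sd = 0, seed = 74)
  mt <- morlet_transform(x, c(8, 10), out_times = sp$time)
  prof <- speed_amplitude_profile(mt, sp)
  expect_true(all(prof$pct_change[prof$speed_bin == 0] == 0))
  # no systematic trend: the running-range mean sits near zero (individual
  # high-speed bins carry Rayleigh envelope sampling noise)
  run_mean <- mean(prof$pct_change[prof$speed_bin >= 10 &
                                     prof$speed_bin < 30])
  expect_lt(abs(run_mean), 3)
})

test_that("signed speed couplings are recovered per band with significance", {
  tr <- simulate_trajectory(600, seed = 75)
  sp <- compute_speed(tr)
  x <- simulate_lfp(600, speed = sp, seed = 76)
  bsp <- band_speed_profile(x, sp)
  truth <- c(delta = -1, theta = 1, beta = -1, gamma = 1)
  for (b in names(truth)) {
    row <- bsp$tests[bsp$tests$band == b, ]
    expect_equal(sign(row$median_pct), unname(truth[b]))
    expect_lt(row$p_value, 0.05)
  }
})

test_that("band boundaries derived from the profile match the generator", {
  tr <- simulate_trajectory(1200, seed = 77)
  sp <- compute_speed(tr)
  x <- simulate_lfp(1200, speed = sp, seed = 78)
  mt <- morlet_transform(x, seq(1, 100, by = 1), out_times = sp$time)
  prof <- speed_amplitude_profile(mt, sp)
  bb <- derive_band_boundaries(prof)
  expect_equal(bb$coupling, c(-1, 1, -1, 1))
  gen <- default_lfp_bands()
  # every between-regime transition of the generator is recovered within
  # one 1-Hz grid step of its edges
  recovered <- sort(unique(c(bb$low, bb$high)))
  transitions <- cbind(gen$high[-nrow(gen)], gen$low[-1])
  for (k in seq_len(nrow(transitions))) {
    expect_lte(min(abs(outer(recovered, transitions[k, ], "-"))), 1)
  }
  # a single positive-coupled band yields one regime (grid restricted to
  # frequencies where the generator puts signal; outside it the amplitude
  # is a noise floor whose profile sign is undefined)
  x1 <- simulate_lfp(600, speed = sp, bands = tibble::tibble(
    band = "theta", low = 6, high = 11, amplitude0 = 50,
    speed_slope = 0.008, carrier_freq = NA), noise_sd = 2, seed = 79)
  mt1 <- morlet_transform(x1, seq(4, 14, by = 1), out_times = sp$time)
  bb1 <- derive_band_boundaries(speed_amplitude_profile(mt1, sp))
  expect_equal(nrow(bb1), 1)
  expect_equal(bb1$coupling, 1)
})

test_that("canonical band constants carry the published edges and signs", {
  cb <- canonical_bands()
  expect_equal(cb$low[cb$band == "delta"], 1)
  expect_equal(cb$high[cb$band == "delta"], 5)
  expect_equal(cb$low[cb$band == "theta"], 6)
  expect_equal(cb$high[cb$band == "theta"], 11)
  expect_equal(cb$low[cb$band == "beta"], 20)
  expect_equal(cb$high[cb$band == "beta"], 30)
  expect_equal(cb$low[cb$band == "gamma"], 35)
  expect_equal(cb$high[cb$band == "gamma"], 100)
  expect_equal(cb$low[cb$band == "ripple"], 120)
  expect_equal(cb$high[cb$band == "ripple"], 240)
  expect_equal(cb$coupling[1:4], c(-1, 1, -1, 1))
})
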