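test_that("the 7 Hz mean-rate cutoff separates cell types, ties to pyramidal", {
  dur <- 100
  sp <- tibble::tibble(
    unit_id = rep(c("slow", "fast", "edge"), c(100, 2000, 700)),
    time = c(sort(runif(100, 0, dur)), sort(runif(2000, 0, dur)),
             sort(runif(700, 0, dur))))
  out <- classify_cell_type(sp, dur)
  expect_equal(out$cell_type[out$unit_id == "slow"], "putative_pyramidal")
  expect_equal(out$cell_type[out$unit_id == "fast"],
               "putative_fast_spiking")
  expect_equal(out$mean_rate[out$unit_id == "edge"], 7)
  expect_equal(out$cell_type[out$unit_id == "edge"], "putative_pyramidal")
  expect_warning(classify_cell_type(numeric(0)[0], 10), "Empty")
})

test_that("mean vector length behaves at its anchors and is rotation-equivariant", {
  expect_equal(mean_vector_length(rep(1.3, 50))$R, 1)
  even <- seq(-pi, pi, length.out = 9)[-9]
  expect_lt(mean_vector_length(even)$R, 1e-12)
  set.seed(81)
  ph <- rvonmises(500, 0.4, 1.5)
  m0 <- mean_vector_length(ph)
  m1 <- mean_vector_length(degumap:::wrap_angle(ph + 1))
  expect_equal(m1$R, m0$R, tolerance = 1e-12)
  expect_equal(degumap:::wrap_angle(m1$mean_phase - m0$mean_phase), 1,
               tolerance = 1e-9)
  expect_true(is.na(mean_vector_length(numeric(0))$R))
})

test_that("kappa-to-R calibration matches the Bessel ratio across kappa", {
  set.seed(82)
  for (k in c(0.5, 1, 2, 4)) {
    R <- mean_vector_length(rvonmises(1e5, 0, k))$R
    expect_lt(abs(R - besselI(k, 1) / besselI(k, 0)), 0.01)
  }
})

test_that("spike phases interpolate correctly across the wrap discontinuity", {
  x <- tone_lfp(8, duration = 30)
  env <- band_envelope(x, c(6, 11))
  # spikes at signal peaks: phase ~ 0 under the positive-peak convention
  peaks <- seq(1 / 32, 29, by = 1 / 8)
  ph <- spike_phases(peaks, env)
  expect_lt(max(abs(ph[5:length(ph)])), 0.05)
  # spikes outside coverage are dropped and counted
  ph2 <- spike_phases(c(-1, 5, 40), env)
  expect_equal(attr(ph2, "n_dropped"), 2)
  expect_equal(length(ph2), 1)
  # uniform spikes give a flat phase histogram
  set.seed(83)
  phu <- spike_phases(runif(1e4, 0, 29), env)
  h <- table(cut(phu, seq(-pi, pi, length.out = 9)))
  expect_gt(chisq.test(h)$p.value, 0.001)
})

# broadband theta LFP: phase drifts, so circular time shifts decorrelate
# spike phases (a pure sinusoid would stay phase-locked under any shift)
theta_noise_lfp <- function(duration, seed) {
  simulate_lfp(duration, bands = tibble::tibble(
    band = "theta", low = 6, high = 11, amplitude0 = 50, speed_slope = 0,
    carrier_freq = NA), noise_sd = 5, seed = seed)
}

test_that("locking significance flags locked units and suppresses low-n results", {
  x <- theta_noise_lfp(300, seed = 840)
  locked <- simulate_phase_locked_spikes(x, c(6, 11), kappa = 2,
                                         mean_rate = 4, seed = 84)
  res <- locking_significance(locked, x, c(6, 11), seed = 85)
  expect_true(res$significant)
  expect_gt(res$R, res$null_p95)
  # single spike: R = 1 but suppressed
  res1 <- locking_significance(150, x, c(6, 11), seed = 86)
  expect_equal(res1$R, 1)
  expect_true(res1$low_n)
  expect_false(res1$significant)
})

test_that("phase-rate curves are dwell-corrected and peak at the preferred phase", {
  x <- tone_lfp(8, duration = 300, amp = 40)
  env <- band_envelope(x, c(6, 11))
  ps <- tibble::tibble(time = env$time, phase = env$phase)
  locked <- simulate_phase_locked_spikes(x, c(6, 11), kappa = 2,
                                         preferred_phase = 0,
                                         mean_rate = 8, seed = 87)
  set.seed(88)
  pois <- poisson_spikes(25, 300)
  curves <- phase_rate_curve(
    tibble::tibble(unit_id = rep(c("locked", "pois"),
                                 c(length(locked), length(pois))),
                   time = c(locked, pois)), ps)
  lk <- curves$curves[curves$curves$unit_id == "locked", ]
  expect_lt(abs(lk$phase_center[which.max(lk$norm_rate)]), pi / 8 + 1e-9)
  po <- curves$curves[curves$curves$unit_id == "pois", ]
  expect_lt(max(abs(po$norm_rate - 1), na.rm = TRUE), 0.25)
})

test_that("phase-rate curves stay flat for Poisson spiking under non-uniform dwell", {
  # oscillator dwelling twice as long near the trough: phase series from a
  # warped clock; a Poisson unit in time must still give a flat curve
  t <- seq(0, 300, by = 5e-4)
  inst_freq <- 8 * (1 + 0.4 * cos(2 * pi * 8 * t))   # slows near trough
  phase <- degumap:::wrap_angle(2 * pi * cumsum(inst_freq) * 5e-4)
  ps <- tibble::tibble(time = t, phase = phase)
  set.seed(89)
  pois <- poisson_spikes(10, 300)
  curves <- phase_rate_curve(tibble::tibble(unit_id = "u", time = pois), ps)
  expect_lt(max(abs(curves$curves$norm_rate - 1), na.rm = TRUE), 0.3)
  # raw counts, by contrast, are far from flat
  counts <- curves$curves$n_spikes
  expect_gt(max(counts) / min(counts[counts > 0]), 1.5)
})

test_that("spike-lag histograms count pairs and show rhythmic peaks", {
  h <- spike_lag_histogram(c(1, 1.1), max_lag = 0.5, bin = 0.01)
  expect_equal(sum(h$count), 1)
  expect_equal(h$count[h$lag > 0.10 & h$lag < 0.11], 1)
  # theta-locked unit: peaks near multiples of 125 ms
  x <- tone_lfp(8, duration = 600, amp = 40)
  locked <- simulate_phase_locked_spikes(x, c(6, 11), kappa = 4,
                                         mean_rate = 6, seed = 90)
  h2 <- spike_lag_histogram(locked, max_lag = 0.3, bin = 0.005)
  near_125 <- h2$count[abs(h2$lag - 0.125) < 0.015]
  near_63 <- h2$count[abs(h2$lag - 0.0625) < 0.015]
  expect_gt(mean(near_125), 1.5 * mean(near_63))
  expect_error(spike_lag_histogram(1), class = "degumap_parameter_error")
})

test_that("pooled phase-locking classification separates locked from unlocked units", {
  x <- theta_noise_lfp(240, seed = 910)
  locked <- simulate_phase_locked_spikes(x, c(6, 11), kappa = 2,
                                         mean_rate = 5, seed = 91)
  set.seed(92)
  unlocked <- poisson_spikes(5, 240)
  sp <- tibble::tibble(
    unit_id = rep(c("locked", "unlocked"),
                  c(length(locked), length(unlocked))),
    time = c(locked, unlocked))
  res <- phase_locking(sp, x, bands = canonical_bands()[2, ],
                       n_shuffles = 50, seed = 93)
  expect_true(res$significant[res$unit_id == "locked"])
  expect_false(res$significant[res$unit_id == "unlocked"])
})
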