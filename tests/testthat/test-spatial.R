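# independent brute-force oracle: two-pass histogram rate map, no smoothing
brute_force_map <- function(spikes, traj, bin_side, arena_side) {
  n_bins <- ceiling(arena_side / bin_side)
  occ <- matrix(0, n_bins, n_bins)
  cnt <- matrix(0, n_bins, n_bins)
  dt <- c(diff(traj$time), median(diff(traj$time)))
  dt[traj$gap_after] <- 0
  for (i in seq_len(nrow(traj))) {
    ix <- min(floor(traj$x[i] / bin_side), n_bins - 1) + 1
    iy <- min(floor(traj$y[i] / bin_side), n_bins - 1) + 1
    occ[ix, iy] <- occ[ix, iy] + dt[i]
  }
  for (s in spikes) {
    j <- findInterval(s, traj$time)
    if (j >= 1 && dt[j] > 0) {
      ix <- min(floor(traj$x[j] / bin_side), n_bins - 1) + 1
      iy <- min(floor(traj$y[j] / bin_side), n_bins - 1) + 1
      cnt[ix, iy] <- cnt[ix, iy] + 1
    }
  }
  rate <- matrix(NA_real_, n_bins, n_bins)
  rate[occ > 0] <- cnt[occ > 0] / occ[occ > 0]
  rate
}

test_that("unsmoothed rate maps equal the brute-force two-pass histogram", {
  tr <- simulate_trajectory(120, arena_side = 30, seed = 31)
  sp <- simulate_place_cell(tr, c(10, 20), width = 6, peak_rate = 8,
                            baseline_rate = 0.5, seed = 32)
  m <- build_rate_map(sp, tr, bin_side = 2.5, smooth_sd_bins = 0)
  oracle <- brute_force_map(sp, tr, 2.5, 30)
  expect_equal(m$rate, oracle)
})

test_that("rate maps satisfy the occupancy/rate conservation identities", {
  tr <- simulate_trajectory(300, seed = 33)
  sp <- simulate_place_cell(tr, c(45, 45), width = 10, peak_rate = 10,
                            baseline_rate = 0.1, seed = 34)
  for (sd_bins in c(0, 1.6)) {
    m <- build_rate_map(sp, tr, smooth_sd_bins = sd_bins)
    expect_lt(abs(sum(m$p) - 1), 1e-9)
    expect_lt(abs(sum(m$p[m$visited] * m$rate[m$visited]) - m$lambda_mean),
              1e-9)
    expect_true(all(is.na(m$rate[!m$visited])))
  }
})

test_that("a single spike in one bin of a uniformly covered grid gives the textbook map", {
  tr <- raster_trajectory(arena_side = 15, step = 2.5)   # 36 bins, equal dwell
  spike_t <- tr$time[5]  # inside the first bin's dwell block
  m <- build_rate_map(spike_t, tr, bin_side = 2.5, smooth_sd_bins = 0)
  occ_per_bin <- m$occupancy[1, 1]
  expect_equal(m$rate[1, 1], 1 / occ_per_bin)
  expect_equal(sum(m$rate > 0, na.rm = TRUE), 1)
})

test_that("homogeneous firing over uniform occupancy gives a flat map at the mean rate", {
  tr <- raster_trajectory(arena_side = 15, step = 2.5,
                          dwell_per_point = 2)
  set.seed(35)
  sp <- poisson_spikes(2, max(tr$time))
  m <- build_rate_map(sp, tr, smooth_sd_bins = 1.6)
  expect_lt(abs(m$lambda_mean - 2), 0.3)
  expect_lt(max(abs(m$rate - m$lambda_mean), na.rm = TRUE), 2)
})

test_that("the information formula evaluates exactly on hand-checkable maps", {
  # two bins, p = (1/2, 1/2), rates (2, 0): lambda = 1,
  # info = 0.5 * 2 * log2(2) = 1 bit/spike and 1 * 1 = 1 bit/s
  m <- two_bin_map(c(2, 0))
  expect_equal(information_score(m, "per_spike"), 1)
  expect_equal(information_score(m, "rate"), 1)
  # uniform map carries no information in either mode
  u <- two_bin_map(c(3, 3))
  expect_equal(information_score(u, "per_spike"), 0)
  expect_equal(information_score(u, "rate"), 0)
})

test_that("information is scale-invariant per spike and 1-homogeneous as a rate", {
  m1 <- two_bin_map(c(4, 1), c(0.3, 0.7))
  m2 <- two_bin_map(c(12, 3), c(0.3, 0.7))
  expect_equal(information_score(m1, "per_spike"),
               information_score(m2, "per_spike"))
  expect_equal(3 * information_score(m1, "rate"),
               information_score(m2, "rate"))
})

test_that("split-half stability behaves at its anchors", {
  # same path and same spike pattern in both halves -> r ~ 1
  tr_half <- simulate_trajectory(300, seed = 36)
  tr <- as_trajectory(tibble::tibble(
    time = c(tr_half$time, tr_half$time + 300.02),
    x = rep(tr_half$x, 2), y = rep(tr_half$y, 2)))
  sp_half <- simulate_place_cell(tr_half, c(30, 30), width = 8,
                                 peak_rate = 12, baseline_rate = 0.2,
                                 seed = 37)
  sp <- c(sp_half, sp_half + 300.02)
  expect_gt(stability_score(sp, tr), 0.9)
  # independent homogeneous halves -> |r| small
  set.seed(38)
  rs <- replicate(10, {
    tr2 <- simulate_trajectory(240, seed = sample.int(1e6, 1))
    stability_score(poisson_spikes(3, 240), tr2)
  })
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("circular shuffles preserve spike count and wrap to identity at shift T", {
  tr <- simulate_trajectory(120, seed = 39)
  sp <- simulate_place_cell(tr, c(45, 45), width = 10, peak_rate = 8,
                            baseline_rate = 0.5, seed = 40)
  t0 <- min(tr$time); T_len <- max(tr$time) - t0
  shifted_T <- sort(((sp - t0 + T_len) %% T_len) + t0)
  m0 <- build_rate_map(sp, tr)
  mT <- build_rate_map(shifted_T, tr)
  expect_equal(information_score(mT), information_score(m0),
               tolerance = 1e-9)
  null <- shuffle_null(sp, tr, function(s, trj) length(s),
                       n_shuffles = 20, seed = 41)
  expect_true(all(null$values == length(sp)))
  expect_error(shuffle_null(sp[1:5], tr[tr$time < 50, ],
                            function(s, trj) 0, min_shift = 30),
               class = "degumap_parameter_error")
})

test_that("pooled-percentile classification uses a strict threshold", {
  null_vals <- seq(0, 1, length.out = 101)   # p95 = 0.95 exactly
  cls <- classify_cells(c(a = 0.9, b = 0.95, c = 0.96), null_vals)
  expect_equal(cls$pass_95, c(FALSE, FALSE, TRUE))
  expect_equal(unname(attr(cls, "thresholds")["p95"]), 0.95)
  expect_error(classify_cells(c(a = 1), numeric(0)),
               class = "degumap_parameter_error")
})

test_that("population p-value matches brute-force summation and its anchors", {
  # direct double-precision oracle for small N
  brute <- function(n, s, q) {
    sum(choose(n, s:n) * q^(s:n) * (1 - q)^(n - (s:n)))
  }
  for (n in c(5, 12, 30)) {
    for (s in c(0, 1, floor(n / 2), n)) {
      for (q in c(0.05, 0.3)) {
        expect_equal(population_pvalue(n, s, q), brute(n, s, q),
                     tolerance = 1e-12)
      }
    }
  }
  expect_equal(population_pvalue(20, 0, 0.05), 1)
  expect_equal(population_pvalue(10, 10, 0.3), 0.3^10, tolerance = 1e-12)
  # agreement with the library tail in log space
  expect_equal(population_pvalue(95, 26, 0.05),
               pbinom(25, 95, 0.05, lower.tail = FALSE), tolerance = 1e-10)
  # strictly decreasing in s
  ps <- vapply(0:20, function(s) population_pvalue(20, s, 0.1), numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(population_pvalue(10, 11, 0.05),
               class = "degumap_parameter_error")
  expect_error(population_pvalue(10, 5, 0),
               class = "degumap_parameter_error")
})

test_that("the observed cell counts are far beyond chance at the reported scale", {
  # 26 of 95 cells above a 95th-percentile criterion: p of order 1e-13
  p <- population_pvalue(95, 26, 0.05)
  expect_gt(p, 1e-14)
  expect_lt(p, 1e-11)
})

test_that("synthetic place cells recover their field centers and stability", {
  centers <- list(c(25, 60), c(60, 25), c(45, 45))
  tr <- simulate_trajectory(1200, seed = 42)
  for (i in seq_along(centers)) {
    sp <- simulate_place_cell(tr, centers[[i]], width = 10, peak_rate = 10,
                              baseline_rate = 0.1, seed = 42 + i)
    m <- build_rate_map(sp, tr)
    peak <- which(m$rate == max(m$rate, na.rm = TRUE), arr.ind = TRUE)[1, ]
    true_bin <- floor(centers[[i]] / 2.5) + 1
    expect_lte(max(abs(peak - true_bin)), 2)
    expect_gt(stability_score(sp, tr), 0.5)
  }
})

test_that("information rate grows with simulated field strength", {
  tr <- simulate_trajectory(900, seed = 50)
  infos <- vapply(c(2, 5, 10, 20), function(pk) {
    sp <- simulate_place_cell(tr, c(40, 50), width = 10, peak_rate = pk,
                              baseline_rate = 0.1, seed = 50 + pk)
    information_score(build_rate_map(sp, tr))
  }, numeric(1))
  expect_true(all(diff(infos) > 0))
})
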