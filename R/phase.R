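#' Classify units as putative pyramidal or fast-spiking by mean rate
#'
#' Mean firing rate at or below the cutoff (7 Hz) labels a unit putative
#' pyramidal; above it, putative fast-spiking. The tie at exactly the
#' cutoff goes to pyramidal. An empty train classifies as pyramidal with a
#' warning.
#'
#' @param spikes_tbl Tibble with `unit_id`, `time`, or a numeric vector of
#'   spike times (single unit).
#' @param duration Session duration in seconds.
#' @param cutoff Rate cutoff in Hz (7).
#' @return Tibble `unit_id`, `n_spikes`, `mean_rate`, `cell_type`.
#' @export
classify_cell_type <- function(spikes_tbl, duration, cutoff = 7) {
  if (duration <= 0) abort("`duration` must be positive.",
                           class = "degumap_parameter_error")
  if (!is.data.frame(spikes_tbl)) {
    spikes_tbl <- tibble(unit_id = "unit", time = as.numeric(spikes_tbl))
  }
  if (nrow(spikes_tbl) == 0) warn("Empty spike train(s); rate 0.")
  counts <- table(factor(spikes_tbl$unit_id))
  tibble(
    unit_id = names(counts),
    n_spikes = as.integer(counts),
    mean_rate = as.integer(counts) / duration,
    cell_type = ifelse(as.integer(counts) / duration > cutoff,
                       "putative_fast_spiking", "putative_pyramidal")
  )
}

#' Band phase at spike times
#'
#' Linearly interpolates the instantaneous band phase at each spike time.
#' Interpolation is done on the unwrapped phase and re-wrapped to
#' (-pi, pi], avoiding artifacts at the +/-pi discontinuity. Spikes outside
#' the phase series' coverage are dropped and counted in the
#' `n_dropped` attribute.
#'
#' @param spikes Numeric spike times (s).
#' @param phase_series Tibble with `time` and `phase` columns (e.g. from
#'   [band_envelope()]).
#' @return Numeric vector of phases in (-pi, pi] with attribute
#'   `n_dropped`.
#' @export
spike_phases <- function(spikes, phase_series) {
  t <- phase_series$time
  inside <- spikes >= t[1] & spikes <= t[length(t)]
  up <- unwrap_phase(phase_series$phase)
  ph <- approx(t, up, xout = spikes[inside])$y
  out <- wrap_angle(ph)
  attr(out, "n_dropped") <- sum(!inside)
  out
}

unwrap_phase <- function(p) {
  d <- diff(p)
  jumps <- cumsum(c(0, round(-d / (2 * pi))))
  p + 2 * pi * jumps
}

# linear interpolator over an unwrapped phase series; exploits uniform
# sampling (the band_envelope clock) for O(#queries) lookups
make_phase_interp <- function(times, unwrapped) {
  n <- length(times)
  dt <- (times[n] - times[1]) / (n - 1)
  uniform <- max(abs(diff(times) - dt)) < dt * 1e-6
  if (uniform) {
    t0 <- times[1]
    function(ts) {
      pos <- (ts - t0) / dt
      i0 <- pmin(pmax(floor(pos), 0), n - 2)
      frac <- pos - i0
      wrap_angle(unwrapped[i0 + 1] * (1 - frac) + unwrapped[i0 + 2] * frac)
    }
  } else {
    function(ts) wrap_angle(approx(times, unwrapped, xout = ts)$y)
  }
}

#' Mean vector length and mean phase of circular data
#'
#' `R = |mean(exp(i phi))|` is 0 for no phase preference and 1 for perfect
#' locking; `mean_phase` is the argument of the mean resultant vector.
#'
#' @param phases Numeric vector of angles in radians.
#' @return List with `R`, `mean_phase`, `n`; `R` and `mean_phase` are `NA`
#'   for empty input.
#' @export
mean_vector_length <- function(phases) {
  n <- length(phases)
  if (n == 0) return(list(R = NA_real_, mean_phase = NA_real_, n = 0L))
  C <- mean(cos(phases))
  S <- mean(sin(phases))
  list(R = sqrt(C^2 + S^2), mean_phase = atan2(S, C), n = n)
}

#' Phase-locking significance by spike-time shuffling
#'
#' Observed mean vector length of a unit's spike phases in a band,
#' compared with R values from circular time shifts of the spike train
#' (same machinery as the spatial shuffles). With fewer than `min_spikes`
#' spikes R is positively biased, so the result is flagged `low_n` and
#' significance suppressed.
#'
#' @param spikes Numeric spike times for one unit.
#' @param x An [lfp_signal()] (or a precomputed phase series tibble with
#'   `time`, `phase`).
#' @param band Length-2 band in Hz (ignored when `x` is a phase series).
#' @param n_shuffles Shuffle repetitions (100).
#' @param min_shift Minimum circular shift (s).
#' @param min_spikes Low-spike-count guard (20).
#' @param seed Optional integer seed.
#' @return One-row tibble: `n_spikes`, `R`, `mean_phase`, `null_p95`,
#'   `significant`, `low_n`, plus a `null_R` list-column with the shuffled
#'   values (pooled across cells by [classify_cells()] callers).
#' @export
locking_significance <- function(spikes, x, band = c(6, 11),
                                 n_shuffles = 100, min_shift = 30,
                                 min_spikes = 20, seed = NULL) {
  phase_series <- if (inherits(x, "lfp")) {
    env <- band_envelope(x, band)
    tibble(time = env$time, phase = env$phase)
  } else as_tibble(x)
  if (!is.null(seed)) set.seed(seed)
  t0 <- phase_series$time[1]
  t1 <- phase_series$time[nrow(phase_series)]
  T_len <- t1 - t0
  if (T_len <= 2 * min_shift) {
    abort("Record shorter than twice the minimum shift.",
          class = "degumap_parameter_error")
  }
  up <- unwrap_phase(phase_series$phase)
  phase_at <- make_phase_interp(phase_series$time, up)
  inside <- spikes >= t0 & spikes <= t1
  sp <- spikes[inside]
  obs <- mean_vector_length(phase_at(sp))
  shifts <- runif(n_shuffles, min_shift, T_len - min_shift)
  null_R <- vapply(shifts, function(s) {
    shifted <- ((sp - t0 + s) %% T_len) + t0
    mean_vector_length(phase_at(shifted))$R
  }, numeric(1))
  p95 <- quantile(null_R, 0.95, names = FALSE)
  low_n <- length(sp) < min_spikes
  tibble(
    n_spikes = length(sp), R = obs$R, mean_phase = obs$mean_phase,
    null_p95 = p95,
    significant = !low_n & !is.na(obs$R) & obs$R > p95,
    low_n = low_n, null_R = list(null_R)
  )
}

#' Phase locking of many units to many bands, with pooled thresholds
#'
#' Runs [locking_significance()] for every unit and band, then replaces the
#' per-unit threshold by the population rule: a unit is significantly
#' modulated by a band when its R exceeds the 95th percentile of the null
#' values pooled over all units for that band (optionally within cell
#' type).
#'
#' @param spikes_tbl Tibble `unit_id`, `time`.
#' @param x An [lfp_signal()].
#' @param bands Band table (`band`, `low`, `high`); default the four
#'   speed-defined canonical bands.
#' @param pool_within Optional tibble `unit_id`, `cell_type`; when given,
#'   nulls are pooled within cell type per band.
#' @param percentile Pooled percentile for significance (95).
#' @inheritParams locking_significance
#' @return Tibble with one row per unit x band: `unit_id`, `band`,
#'   `n_spikes`, `R`, `mean_phase`, `pooled_p95`, `significant`, `low_n`.
#' @export
phase_locking <- function(spikes_tbl, x, bands = canonical_bands()[1:4, ],
                          pool_within = NULL, n_shuffles = 100,
                          min_shift = 30, min_spikes = 20, percentile = 95,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  units <- unique(spikes_tbl$unit_id)
  rows <- vector("list", nrow(bands) * length(units))
  k <- 0
  for (b in seq_len(nrow(bands))) {
    env <- band_envelope(x, c(bands$low[b], bands$high[b]))
    ps <- tibble(time = env$time, phase = env$phase)
    for (u in units) {
      sp <- spikes_tbl$time[spikes_tbl$unit_id == u]
      res <- locking_significance(sp, ps, n_shuffles = n_shuffles,
                                  min_shift = min_shift,
                                  min_spikes = min_spikes)
      res$unit_id <- u
      res$band <- bands$band[b]
      k <- k + 1
      rows[[k]] <- res
    }
  }
  out <- bind_rows(rows)
  if (!is.null(pool_within)) {
    out <- left_join(out, pool_within, by = "unit_id")
    grp <- c("band", "cell_type")
  } else grp <- "band"
  out <- out |>
    group_by(across(all_of(grp))) |>
    mutate(pooled_p95 = quantile(unlist(.data$null_R), percentile / 100,
                                 names = FALSE)) |>
    ungroup() |>
    mutate(significant = !.data$low_n & !is.na(.data$R) &
             .data$R > .data$pooled_p95)
  select(out, -"null_R", -"null_p95")
}

#' Normalized firing rate as a function of oscillation phase
#'
#' Per unit: spike count per phase bin divided by the time the oscillation
#' spent in that bin (dwell-time correction), normalized by the unit's mean
#' rate so every cell contributes with equal weight; population mean and
#' s.e.m. per bin; circular mean of the population curve (curve values used
#' as weights on the bin-center directions).
#'
#' @param spikes_tbl Tibble `unit_id`, `time` (one or many units).
#' @param phase_series Tibble `time`, `phase` for the band.
#' @param n_bins Number of phase bins (16).
#' @return List with `curves` (unit_id, bin, phase_center, n_spikes,
#'   dwell_s, norm_rate), `population` (bin, phase_center, mean, sem, n),
#'   and `circular_mean` (radians).
#' @export
phase_rate_curve <- function(spikes_tbl, phase_series, n_bins = 16) {
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  centers <- edges[-1] - diff(edges) / 2
  dt <- median(diff(phase_series$time))
  dwell <- tapply(rep(dt, nrow(phase_series)),
                  factor(findInterval(phase_series$phase, edges,
                                      rightmost.closed = TRUE),
                         levels = seq_len(n_bins)), sum)
  dwell <- ifelse(is.na(dwell), 0, dwell)
  total_t <- nrow(phase_series) * dt
  units <- unique(spikes_tbl$unit_id)
  rows <- vector("list", length(units))
  for (i in seq_along(units)) {
    sp <- spikes_tbl$time[spikes_tbl$unit_id == units[i]]
    ph <- spike_phases(sp, phase_series)
    counts <- tapply(rep(1, length(ph)),
                     factor(findInterval(ph, edges, rightmost.closed = TRUE),
                            levels = seq_len(n_bins)), sum)
    counts <- ifelse(is.na(counts), 0, counts)
    mean_rate <- length(ph) / total_t
    norm_rate <- ifelse(dwell > 0, (counts / dwell) / mean_rate, NA_real_)
    rows[[i]] <- tibble(unit_id = units[i], bin = seq_len(n_bins),
                        phase_center = centers,
                        n_spikes = as.numeric(counts),
                        dwell_s = as.numeric(dwell),
                        norm_rate = as.numeric(norm_rate))
  }
  curves <- bind_rows(rows)
  population <- curves |>
    group_by(.data$bin, .data$phase_center) |>
    summarise(mean = mean(.data$norm_rate, na.rm = TRUE),
              sem = stats::sd(.data$norm_rate, na.rm = TRUE) /
                sqrt(sum(!is.na(.data$norm_rate))),
              n = sum(!is.na(.data$norm_rate)), .groups = "drop")
  w <- population$mean
  cm <- atan2(sum(w * sin(population$phase_center), na.rm = TRUE),
              sum(w * cos(population$phase_center), na.rm = TRUE))
  list(curves = curves, population = population, circular_mean = cm)
}

#' Spike-lag (autocorrelogram) histogram
#'
#' Counts spike-pair lags in (0, max_lag], excluding self-pairs; the
#' display convention is symmetric around zero.
#'
#' @param spikes Sorted numeric spike times (s).
#' @param max_lag Maximum lag in seconds (0.5).
#' @param bin Bin width in seconds (0.01).
#' @return Tibble with `lag` (bin center, positive side) and `count`.
#' @export
spike_lag_histogram <- function(spikes, max_lag = 0.5, bin = 0.01) {
  if (length(spikes) < 2) {
    abort("Need at least 2 spikes.", class = "degumap_parameter_error")
  }
  spikes <- sort(spikes)
  n <- length(spikes)
  hi <- findInterval(spikes + max_lag, spikes)
  lags <- unlist(lapply(seq_len(n), function(i) {
    if (hi[i] > i) spikes[(i + 1):hi[i]] - spikes[i] else numeric(0)
  }))
  lags <- lags[lags > 0 & lags <= max_lag]
  n_bins <- ceiling(max_lag / bin)
  counts <- tabulate(pmin(floor(lags / bin) + 1, n_bins), nbins = n_bins)
  tibble(lag = (seq_len(n_bins) - 0.5) * bin, count = counts)
}
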