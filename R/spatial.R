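#' Build an occupancy-normalized spatial rate map
#'
#' Positions are binned on a square grid of `bin_side` cm (half-open bins,
#' origin at the arena's south-west corner). The raw map is spike count
#' divided by time spent per bin; the map is then smoothed with a 2D
#' Gaussian kernel (sd in bin units) whose weights are renormalized over
#' visited bins only, so no rate leaks into unvisited space and unvisited
#' bins stay undefined. Occupancy probabilities and the occupancy-weighted
#' mean rate are recomputed from the smoothed map, and the conservation
#' identities `sum(p) = 1` and `lambda = sum(p * rate)` are asserted.
#'
#' @param spikes Numeric vector of spike times (s) for one unit.
#' @param traj A [as_trajectory()] tibble.
#' @param bin_side Bin side in cm (2.5).
#' @param smooth_sd_bins Gaussian smoothing sd in bin units (1.6); 0 for no
#'   smoothing.
#' @return An object of class `rate_map`: list with `rate`, `occupancy`,
#'   `p` (matrices, x by y, `NA` in unvisited bins of `rate`), `lambda_mean`,
#'   `bin_side`, `arena_side`, `n_spikes_used`, `n_spikes_dropped`.
#' @export
build_rate_map <- function(spikes, traj, bin_side = 2.5,
                           smooth_sd_bins = 1.6) {
  arena_side <- attr(traj, "arena_side") %||% 90
  n_bins <- ceiling(arena_side / bin_side)
  geom <- rate_map_geometry(traj, bin_side, n_bins)
  spike_bins <- spikes_to_bins(spikes, traj, geom)
  finish_rate_map(geom, spike_bins$bins, spike_bins$dropped,
                  smooth_sd_bins, bin_side, arena_side)
}

# Precompute everything that depends on the trajectory alone (reused
# across shuffles): per-sample bin index, dwell weights, occupancy matrix.
rate_map_geometry <- function(traj, bin_side, n_bins) {
  ix <- pmin(floor(traj$x / bin_side), n_bins - 1) + 1
  iy <- pmin(floor(traj$y / bin_side), n_bins - 1) + 1
  bin <- (iy - 1) * n_bins + ix
  dwell <- trajectory_dwell(traj)
  occ <- matrix(0, n_bins, n_bins)
  tot <- tapply(dwell, factor(bin, levels = seq_len(n_bins^2)), sum)
  occ[] <- ifelse(is.na(tot), 0, tot)
  if (sum(occ) <= 0) {
    abort("Zero total occupancy.", class = "degumap_validation_error")
  }
  list(bin = bin, dwell = dwell, occ = occ, n_bins = n_bins,
       time = traj$time)
}

spikes_to_bins <- function(spikes, traj, geom) {
  n <- length(geom$time)
  idx <- findInterval(spikes, geom$time)
  in_range <- idx >= 1 & spikes <= geom$time[n] + (geom$time[n] - geom$time[n - 1])
  valid <- in_range
  valid[in_range] <- geom$dwell[idx[in_range]] > 0
  list(bins = geom$bin[idx[valid]], dropped = sum(!valid))
}

finish_rate_map <- function(geom, spike_bin_idx, dropped, smooth_sd_bins,
                            bin_side, arena_side) {
  n_bins <- geom$n_bins
  counts <- matrix(0, n_bins, n_bins)
  if (length(spike_bin_idx) > 0) {
    tb <- tabulate(spike_bin_idx, nbins = n_bins^2)
    counts[] <- tb
  }
  visited <- geom$occ > 0
  raw <- matrix(NA_real_, n_bins, n_bins)
  raw[visited] <- counts[visited] / geom$occ[visited]
  rate <- if (smooth_sd_bins > 0) {
    smooth_masked(raw, visited, smooth_sd_bins)
  } else raw
  p <- geom$occ / sum(geom$occ)
  lambda <- sum(p[visited] * rate[visited])
  stopifnot(abs(sum(p) - 1) < 1e-9)
  structure(
    list(rate = rate, occupancy = geom$occ, p = p, visited = visited,
         lambda_mean = lambda, bin_side = bin_side, arena_side = arena_side,
         n_spikes_used = length(spike_bin_idx), n_spikes_dropped = dropped),
    class = "rate_map"
  )
}

# Gaussian smoothing with the kernel renormalized over visited bins only.
smooth_masked <- function(raw, mask, sd_bins) {
  half <- max(1L, ceiling(4 * sd_bins))
  off <- -half:half
  k1 <- exp(-off^2 / (2 * sd_bins^2))
  kern <- outer(k1, k1)
  z <- raw
  z[!mask] <- 0
  m <- matrix(as.numeric(mask), nrow(raw), ncol(raw))
  num <- conv2_shift(z, kern, off)
  den <- conv2_shift(m, kern, off)
  out <- matrix(NA_real_, nrow(raw), ncol(raw))
  out[mask] <- num[mask] / den[mask]
  out
}

# dense 2D convolution by shifted adds (kernels are small)
conv2_shift <- function(x, kern, off) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (a in seq_along(off)) {
    da <- off[a]
    if (abs(da) >= nr) next
    r_src <- max(1, 1 + da):min(nr, nr + da)
    r_dst <- max(1, 1 - da):min(nr, nr - da)
    for (b in seq_along(off)) {
      w <- kern[a, b]
      db <- off[b]
      if (abs(db) >= nc) next
      c_src <- max(1, 1 + db):min(nc, nc + db)
      c_dst <- max(1, 1 - db):min(nc, nc - db)
      out[r_dst, c_dst] <- out[r_dst, c_dst] + w * x[r_src, c_src]
    }
  }
  out
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("<rate_map> %dx%d bins of %g cm, %d spikes, mean rate %.3f Hz, peak %.3f Hz\n",
              nrow(x$rate), ncol(x$rate), x$bin_side, x$n_spikes_used,
              x$lambda_mean, max(x$rate, na.rm = TRUE)))
  invisible(x)
}

#' @export
tidy.rate_map <- function(x, ...) {
  n <- nrow(x$rate)
  grid <- expand.grid(bin_x = seq_len(n), bin_y = seq_len(n))
  bs <- x$bin_side
  occ <- as.vector(x$occupancy)
  pp <- as.vector(x$p)
  rr <- as.vector(x$rate)
  tibble(
    bin_x = grid$bin_x, bin_y = grid$bin_y,
    x = (grid$bin_x - 0.5) * bs,
    y = (grid$bin_y - 0.5) * bs,
    occupancy_s = occ, p = pp, rate = rr
  )
}

#' @export
glance.rate_map <- function(x, ...) {
  tibble(
    n_bins_visited = sum(x$visited),
    lambda_mean = x$lambda_mean,
    peak_rate = max(x$rate, na.rm = TRUE),
    information_per_spike = information_score(x, "per_spike"),
    information_rate = information_score(x, "rate"),
    n_spikes = x$n_spikes_used
  )
}

#' Skaggs spatial information of a rate map
#'
#' `per_spike` mode evaluates `sum_i p_i (lambda_i / lambda) log2(lambda_i /
#' lambda)` in bits per spike (with `0 log 0 = 0`); `rate` mode multiplies
#' by the mean rate `lambda`, giving the information rate in bits per
#' second — the form in which classification thresholds are quoted.
#'
#' @param map A [build_rate_map()] result.
#' @param mode `"rate"` (bits/s, default) or `"per_spike"` (bits/spike).
#' @return Non-negative scalar; 0 (with a warning) when the mean rate is 0.
#' @export
information_score <- function(map, mode = c("rate", "per_spike")) {
  mode <- match.arg(mode)
  lambda <- map$lambda_mean
  if (lambda <= 0) {
    warn("Mean rate is zero; information defined as 0.")
    return(0)
  }
  p <- map$p[map$visited]
  r <- map$rate[map$visited] / lambda
  terms <- ifelse(r > 0, p * r * log2(r), 0)
  per_spike <- max(sum(terms), 0)
  if (mode == "per_spike") per_spike else lambda * per_spike
}

#' Split-half stability of a spatial map
#'
#' Pearson correlation between the smoothed rate maps built from the first
#' and second halves of the session (split at the time midpoint), over bins
#' visited in both halves.
#'
#' @inheritParams build_rate_map
#' @param min_joint_bins Result is `NA` (undefined) when fewer bins are
#'   visited in both halves.
#' @return Correlation in `[-1, 1]`, or `NA` with attribute
#'   `n_joint_bins` when undefined.
#' @export
stability_score <- function(spikes, traj, bin_side = 2.5,
                            smooth_sd_bins = 1.6, min_joint_bins = 10) {
  t_mid <- (min(traj$time) + max(traj$time)) / 2
  first <- traj[traj$time < t_mid, ]
  second <- traj[traj$time >= t_mid, ]
  attr(first, "arena_side") <- attr(traj, "arena_side")
  attr(second, "arena_side") <- attr(traj, "arena_side")
  m1 <- build_rate_map(spikes[spikes < t_mid], first, bin_side, smooth_sd_bins)
  m2 <- build_rate_map(spikes[spikes >= t_mid], second, bin_side,
                       smooth_sd_bins)
  joint <- m1$visited & m2$visited
  n_joint <- sum(joint)
  if (n_joint < min_joint_bins) {
    out <- NA_real_
    attr(out, "n_joint_bins") <- n_joint
    return(out)
  }
  r <- stats::cor(m1$rate[joint], m2$rate[joint])
  attr(r, "n_joint_bins") <- n_joint
  r
}

#' Shuffle null distribution by circular spike-time shifts
#'
#' Each repetition shifts the whole spike train along the trajectory by a
#' random interval drawn uniformly in `[min_shift, T - min_shift]` seconds,
#' wrapping the end of the session to the beginning (spike count is
#' preserved exactly), and recomputes the statistic on the shifted train.
#'
#' @param spikes Numeric spike times for one unit.
#' @param traj Trajectory tibble.
#' @param statistic Function `(spikes, traj) -> numeric(1)`.
#' @param n_shuffles Number of repetitions.
#' @param min_shift Minimum shift in seconds (30).
#' @param seed Optional integer seed.
#' @return Object of class `shuffle_null`: list with `values`,
#'   `n_shuffles`, `statistic_name`.
#' @export
shuffle_null <- function(spikes, traj, statistic, n_shuffles = 1000,
                         min_shift = 30, seed = NULL,
                         statistic_name = "statistic") {
  t0 <- min(traj$time)
  t1 <- max(traj$time)
  T_len <- t1 - t0
  if (T_len <= 2 * min_shift) {
    abort("Session shorter than twice the minimum shift.",
          class = "degumap_parameter_error")
  }
  if (!is.null(seed)) set.seed(seed)
  shifts <- runif(n_shuffles, min_shift, T_len - min_shift)
  values <- vapply(shifts, function(s) {
    shifted <- sort(((spikes - t0 + s) %% T_len) + t0)
    statistic(shifted, traj)
  }, numeric(1))
  structure(list(values = values, n_shuffles = n_shuffles,
                 statistic_name = statistic_name),
            class = "shuffle_null")
}

#' @export
print.shuffle_null <- function(x, ...) {
  cat(sprintf("<shuffle_null> %s: %d values, p95 = %.4g, p99 = %.4g\n",
              x$statistic_name, length(x$values),
              quantile(x$values, 0.95), quantile(x$values, 0.99)))
  invisible(x)
}

#' @export
quantile.shuffle_null <- function(x, probs, ...) {
  quantile(x$values, probs, names = FALSE, ...)
}

#' @export
tidy.shuffle_null <- function(x, ...) {
  tibble(statistic = x$statistic_name, value = x$values)
}

#' @export
glance.shuffle_null <- function(x, ...) {
  tibble(statistic = x$statistic_name, n = length(x$values),
         p95 = quantile(x$values, 0.95), p99 = quantile(x$values, 0.99))
}

#' Per-unit spatial scores with pooled shuffle nulls
#'
#' For every unit: information rate, information per spike, split-half
#' stability, and `n_shuffles` circular-shift null values of the
#' information statistic (and of stability when `stability_null` is TRUE).
#' The per-unit nulls are pooled by [classify_cells()] for thresholding.
#'
#' Uses a fast path: trajectory binning and occupancy are computed once and
#' reused across all shuffles of all units.
#'
#' @param spikes_tbl Tibble with `unit_id`, `time`.
#' @param traj Trajectory tibble.
#' @param n_shuffles Shuffles per cell (1000 for spatial statistics).
#' @param mode Information mode passed to [information_score()].
#' @param stability_null Also build the stability null (slower).
#' @param seed Optional integer seed.
#' @inheritParams build_rate_map
#' @return List with `scores` (tibble: unit_id, n_spikes, information,
#'   information_per_spike, stability) and `null_information`,
#'   `null_stability` (tibbles unit_id, value).
#' @export
spatial_scores <- function(spikes_tbl, traj, n_shuffles = 1000,
                           bin_side = 2.5, smooth_sd_bins = 1.6,
                           min_shift = 30, mode = "rate",
                           stability_null = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  arena_side <- attr(traj, "arena_side") %||% 90
  n_bins <- ceiling(arena_side / bin_side)
  geom <- rate_map_geometry(traj, bin_side, n_bins)
  t0 <- min(traj$time); t1 <- max(traj$time); T_len <- t1 - t0
  info_of <- function(sp) {
    sb <- spikes_to_bins(sp, traj, geom)
    m <- finish_rate_map(geom, sb$bins, sb$dropped, smooth_sd_bins,
                         bin_side, arena_side)
    information_score(m, mode)
  }
  units <- unique(spikes_tbl$unit_id)
  scores <- vector("list", length(units))
  nulls_i <- vector("list", length(units))
  nulls_s <- vector("list", length(units))
  for (u in seq_along(units)) {
    sp <- spikes_tbl$time[spikes_tbl$unit_id == units[u]]
    info <- info_of(sp)
    m <- build_rate_map(sp, traj, bin_side, smooth_sd_bins)
    stab <- stability_score(sp, traj, bin_side, smooth_sd_bins)
    shifts <- runif(n_shuffles, min_shift, T_len - min_shift)
    vals <- vapply(shifts, function(s) {
      info_of(sort(((sp - t0 + s) %% T_len) + t0))
    }, numeric(1))
    nulls_i[[u]] <- tibble(unit_id = units[u], value = vals)
    if (stability_null) {
      vals_s <- vapply(shifts, function(s) {
        as.numeric(stability_score(sort(((sp - t0 + s) %% T_len) + t0),
                                   traj, bin_side, smooth_sd_bins))
      }, numeric(1))
      nulls_s[[u]] <- tibble(unit_id = units[u], value = vals_s)
    }
    scores[[u]] <- tibble(
      unit_id = units[u], n_spikes = length(sp),
      information = info,
      information_per_spike = information_score(m, "per_spike"),
      stability = as.numeric(stab)
    )
  }
  list(scores = bind_rows(scores),
       null_information = bind_rows(nulls_i),
       null_stability = if (stability_null) bind_rows(nulls_s) else NULL)
}

#' Classify cells against pooled shuffle percentiles
#'
#' Thresholds are percentiles (linear interpolation between order
#' statistics) of the pooled null — all cells' shuffled values together — and
#' a cell passes a threshold with a strict inequality.
#'
#' @param values Tibble with `unit_id` and `value` (the observed statistic),
#'   or a named numeric vector.
#' @param null A [shuffle_null()] object, a numeric vector of pooled null
#'   values, or a tibble with a `value` column.
#' @param percentiles Percentiles to threshold at (95, 99).
#' @return Tibble with `unit_id`, `value` and a logical `pass_<p>` column
#'   per percentile; threshold values in the `thresholds` attribute (also
#'   via `glance`-style inspection).
#' @export
classify_cells <- function(values, null, percentiles = c(95, 99)) {
  if (!is.data.frame(values)) {
    values <- tibble(unit_id = names(values) %||%
                       as.character(seq_along(values)),
                     value = as.numeric(values))
  }
  null_values <- if (inherits(null, "shuffle_null")) null$values
  else if (is.data.frame(null)) null$value
  else as.numeric(null)
  if (length(null_values) == 0) {
    abort("Empty null distribution.", class = "degumap_parameter_error")
  }
  thr <- quantile(null_values, percentiles / 100, names = FALSE, type = 7)
  out <- values
  for (i in seq_along(percentiles)) {
    out[[sprintf("pass_%g", percentiles[i])]] <- out$value > thr[i]
  }
  attr(out, "thresholds") <- stats::setNames(thr,
                                             sprintf("p%g", percentiles))
  out
}

#' Binomial tail probability for a subpopulation size
#'
#' Probability of observing `s` or more successes out of `n` Bernoulli
#' trials with success probability `success_prob` — used to ask whether the
#' number of cells passing a chance-level percentile threshold exceeds the
#' count expected by chance. Computed as a log-space sum of exact binomial
#' terms, so it stays accurate at p-values far below double-precision
#' granularity of naive summation.
#'
#' @param n Population size.
#' @param s Subpopulation (passing) size.
#' @param success_prob Per-cell chance probability (e.g. 0.05 for a 95th
#'   percentile criterion).
#' @return Upper-tail probability in (0, 1].
#' @export
population_pvalue <- function(n, s, success_prob) {
  if (!(n >= 0 && s >= 0 && s <= n)) {
    abort("Need 0 <= s <= n.", class = "degumap_parameter_error")
  }
  if (!(success_prob > 0 && success_prob < 1)) {
    abort("`success_prob` must be in (0, 1).",
          class = "degumap_parameter_error")
  }
  if (s == 0) return(1)
  lp <- dbinom(s:n, n, success_prob, log = TRUE)
  m <- max(lp)
  exp(m + log(sum(exp(lp - m))))
}
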