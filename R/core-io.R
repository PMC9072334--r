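#' Validate a tracking table as a trajectory
#'
#' Takes a data frame of tracked positions (columns `time`, `x`, `y`; the
#' on-disk aliases `t_s`, `x_cm`, `y_cm` are accepted) and returns a
#' validated trajectory tibble. Positions are clamped to the arena bounds
#' (the number of clamped samples is recorded in the QC attribute, never
#' silently), times must be strictly increasing, and sampling gaps longer
#' than `gap_s` are flagged in the `gap_after` column so occupancy and speed
#' computations can exclude them instead of interpolating across them.
#'
#' Coordinates are in cm with the origin at the arena's south-west corner.
#'
#' @param df Data frame with columns `time`, `x`, `y` (s, cm, cm).
#' @param arena_side Arena side in cm (90 cm open field by default).
#' @param gap_s Sampling gaps longer than this (s) are flagged.
#' @return A tibble of class `trajectory` with columns `time`, `x`, `y`,
#'   `gap_after`; attributes `arena_side` and `qc` (list with `n_clamped`,
#'   `n_gaps`).
#' @export
as_trajectory <- function(df, arena_side = 90, gap_s = 0.5) {
  df <- as_tibble(df)
  ren <- c(time = "t_s", x = "x_cm", y = "y_cm")
  for (nm in names(ren)) {
    if (!nm %in% names(df) && ren[[nm]] %in% names(df)) {
      names(df)[names(df) == ren[[nm]]] <- nm
    }
  }
  for (nm in c("time", "x", "y")) {
    if (!nm %in% names(df)) {
      abort(sprintf("Tracking data is missing required column `%s`.", nm),
            class = "degumap_format_error")
    }
  }
  if (anyNA(df[c("time", "x", "y")])) {
    abort("Tracking data contains missing values.",
          class = "degumap_format_error")
  }
  if (is.unsorted(df$time, strictly = TRUE)) {
    abort("Tracking times must be strictly increasing.",
          class = "degumap_validation_error")
  }
  clamped <- sum(df$x < 0 | df$x > arena_side | df$y < 0 | df$y > arena_side)
  df$x <- pmin(pmax(df$x, 0), arena_side)
  df$y <- pmin(pmax(df$y, 0), arena_side)
  dt <- c(diff(df$time), NA)
  df$gap_after <- !is.na(dt) & dt > gap_s
  out <- df[c("time", "x", "y", "gap_after")]
  attr(out, "arena_side") <- arena_side
  attr(out, "qc") <- list(n_clamped = clamped, n_gaps = sum(df$gap_after))
  class(out) <- c("trajectory", class(out))
  out
}

#' @export
print.trajectory <- function(x, ...) {
  qc <- attr(x, "qc")
  cat(sprintf("<trajectory> %d samples, %.1f s, arena %g cm (%d clamped, %d gaps)\n",
              nrow(x), diff(range(x$time)), attr(x, "arena_side"),
              qc$n_clamped, qc$n_gaps))
  NextMethod()
}

# per-sample occupancy weights (s): time to next sample, capped at the gap
# threshold (gap samples contribute 0); the last sample gets the median step.
trajectory_dwell <- function(traj, gap_s = 0.5) {
  dt <- diff(traj$time)
  dt <- c(dt, median(dt))
  dt[traj$gap_after] <- 0
  dt
}

#' Instantaneous running speed from a trajectory
#'
#' Speed is the Euclidean displacement across a time window divided by the
#' elapsed time, evaluated per tracking sample with a centered window
#' (trailing/leading at the record edges). The 200 ms default matches the
#' temporal resolution of 50 Hz video tracking.
#'
#' @param traj A [as_trajectory()] tibble.
#' @param window Window length in seconds (default 0.2).
#' @return A tibble of class `speed_series` with columns `time`,
#'   `speed` (cm/s); `speed` is `NA` where the window spans a tracking gap.
#' @export
compute_speed <- function(traj, window = 0.2) {
  if (!is.numeric(window) || length(window) != 1 || window <= 0) {
    abort("`window` must be a single positive number of seconds.",
          class = "degumap_parameter_error")
  }
  n <- nrow(traj)
  if (n < 2) abort("Need at least two tracking samples.")
  dt_med <- median(diff(traj$time))
  k <- max(1L, as.integer(round((window / 2) / dt_med)))
  i <- seq_len(n)
  lo <- pmax(1L, i - k)
  hi <- pmin(n, lo + 2L * k)
  lo <- pmax(1L, hi - 2L * k)
  span <- traj$time[hi] - traj$time[lo]
  d <- sqrt((traj$x[hi] - traj$x[lo])^2 + (traj$y[hi] - traj$y[lo])^2)
  speed <- d / span
  # invalidate windows that straddle a flagged gap
  gap_cum <- cumsum(c(FALSE, traj$gap_after[-n]))
  has_gap <- gap_cum[hi] - gap_cum[lo] > 0
  speed[has_gap | !is.finite(speed)] <- NA_real_
  out <- tibble(time = traj$time, speed = speed)
  attr(out, "window") <- window
  class(out) <- c("speed_series", class(out))
  out
}

#' Consecutive non-overlapping windows with per-window series means
#'
#' Splits a time range into consecutive left-aligned windows of fixed
#' width, dropping the final partial window, and (optionally) attaches the
#' mean of a sampled series per window. This is the common windowing used
#' for 2 s spectral windows, 30 s exploration windows, and 1 min event-rate
#' windows.
#'
#' @param times Length-2 numeric `c(start, end)` in seconds, or a numeric
#'   vector whose range is used.
#' @param width Window width in seconds.
#' @param series Optional data frame with columns `time` and a value column
#'   (the second column, or `value`) to average per window.
#' @return A tibble with `window`, `t_start`, `t_end` and, when `series` is
#'   supplied, `mean_value` (NA-removed mean) and `n` samples.
#' @export
window_segments <- function(times, width, series = NULL) {
  if (!is.numeric(width) || length(width) != 1 || width <= 0) {
    abort("`width` must be a single positive number of seconds.",
          class = "degumap_parameter_error")
  }
  t0 <- min(times)
  t1 <- max(times)
  n_win <- floor((t1 - t0) / width)
  if (n_win < 1) {
    return(tibble(window = integer(), t_start = numeric(),
                  t_end = numeric()))
  }
  out <- tibble(
    window = seq_len(n_win),
    t_start = t0 + (seq_len(n_win) - 1) * width,
    t_end = t0 + seq_len(n_win) * width
  )
  if (!is.null(series)) {
    series <- as_tibble(series)
    value_col <- if ("value" %in% names(series)) "value" else names(series)[2]
    idx <- floor((series$time - t0) / width) + 1
    keep <- idx >= 1 & idx <= n_win & series$time < t0 + n_win * width
    means <- tapply(series[[value_col]][keep], factor(idx[keep],
                    levels = seq_len(n_win)), mean, na.rm = TRUE)
    counts <- tapply(rep(1, sum(keep)), factor(idx[keep],
                     levels = seq_len(n_win)), sum)
    out$mean_value <- as.numeric(means)
    out$n <- ifelse(is.na(counts), 0L, as.integer(counts))
  }
  out
}

#' Low-pass filter and downsample a raw LFP trace to 2 kHz
#'
#' Applies a zero-phase (forward-backward) 4th-order Butterworth low-pass
#' at 1 kHz and decimates to the target rate. Input already at the target
#' rate is returned unchanged (the 1 kHz cutoff is then the Nyquist
#' frequency and there is nothing to remove), which makes the operation
#' idempotent.
#'
#' @param x An [lfp_signal()] at any rate >= 2 kHz; the rate must be an
#'   integer multiple of `target_rate`.
#' @param target_rate Output rate in Hz (2000).
#' @param cutoff Low-pass cutoff in Hz (1000).
#' @return An `lfp` object at `target_rate`.
#' @export
preprocess_lfp <- function(x, target_rate = 2000, cutoff = 1000) {
  stopifnot(inherits(x, "lfp"))
  if (x$rate < target_rate) {
    abort(sprintf("LFP rate %g Hz is below the target %g Hz; nothing to do or would alias.",
                  x$rate, target_rate), class = "degumap_parameter_error")
  }
  if (x$rate == target_rate) return(x)
  factor <- x$rate / target_rate
  if (abs(factor - round(factor)) > 1e-9) {
    abort("LFP rate must be an integer multiple of the target rate.",
          class = "degumap_parameter_error")
  }
  bf <- signal::butter(4, cutoff / (x$rate / 2), type = "low")
  filtered <- signal::filtfilt(bf, x$samples)
  idx <- seq(1, length(filtered), by = round(factor))
  lfp_signal(filtered[idx], target_rate, t0 = x$t0,
             channel_id = x$channel_id, tetrode_id = x$tetrode_id)
}

#' Assemble a validated session record
#'
#' @param session_type One of `"rest"`, `"open_field"`, `"sample"`, `"test"`.
#' @param duration Session duration in seconds.
#' @param spikes Tibble with columns `unit_id`, `time` (s), sorted per unit.
#' @param trajectory A [as_trajectory()] tibble, or NULL (rest sessions).
#' @param lfp Named list of [lfp_signal()] objects.
#' @param objects Tibble with columns `label`, `x`, `y` (cm); only sample
#'   and test sessions may carry objects.
#' @param arena_side Arena side in cm.
#' @return A list of class `session_record`.
#' @export
session_record <- function(session_type, duration, spikes = NULL,
                           trajectory = NULL, lfp = list(), objects = NULL,
                           arena_side = 90) {
  types <- c("rest", "open_field", "sample", "test")
  if (!session_type %in% types) {
    abort(sprintf("`session_type` must be one of %s.",
                  paste(types, collapse = ", ")),
          class = "degumap_validation_error")
  }
  if (!is.null(objects) && nrow(objects) > 0 &&
      !session_type %in% c("sample", "test")) {
    abort("Only sample/test sessions carry objects.",
          class = "degumap_validation_error")
  }
  if (is.null(spikes)) spikes <- tibble(unit_id = character(), time = numeric())
  spikes <- as_tibble(spikes)
  if (!all(c("unit_id", "time") %in% names(spikes))) {
    abort("`spikes` needs columns `unit_id` and `time`.",
          class = "degumap_format_error")
  }
  bad <- spikes$time < 0 | spikes$time > duration
  if (any(bad)) {
    warn(sprintf("%d spikes outside [0, duration] dropped.", sum(bad)))
    spikes <- spikes[!bad, ]
  }
  unsorted <- vapply(split(spikes$time, spikes$unit_id),
                     is.unsorted, logical(1))
  if (any(unsorted)) {
    abort("Spike timestamps must be sorted within each unit.",
          class = "degumap_validation_error")
  }
  # streams must share the session clock: tolerate at most 1 s of mismatch
  for (ch in lfp) {
    if (abs(lfp_duration(ch) - duration) > 1) {
      abort(sprintf("LFP channel %s duration %.1f s disagrees with session duration %.1f s.",
                    ch$channel_id, lfp_duration(ch), duration),
            class = "degumap_alignment_error")
    }
  }
  if (!is.null(trajectory) && abs(max(trajectory$time) - duration) > 1) {
    abort("Tracking clock disagrees with session duration by more than 1 s.",
          class = "degumap_alignment_error")
  }
  structure(
    list(session_type = session_type, duration = duration, spikes = spikes,
         trajectory = trajectory, lfp = lfp,
         objects = objects %||% tibble(label = character(), x = numeric(),
                                       y = numeric()),
         arena_side = arena_side),
    class = "session_record"
  )
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record> %s, %.0f s: %d units, %s tracking, %d LFP channel(s), %d object(s)\n",
              x$session_type, x$duration,
              length(unique(x$spikes$unit_id)),
              if (is.null(x$trajectory)) "no" else sprintf("%d-sample", nrow(x$trajectory)),
              length(x$lfp), nrow(x$objects)))
  invisible(x)
}

#' Write a session to a directory of plain-text + binary files
#'
#' On-disk layout: `spikes.csv` (`unit_id,timestamp_s`), `tracking.csv`
#' (`t_s,x_cm,y_cm`), `lfp.bin` (little-endian float32, frames interleaved
#' across channels) with sidecar `lfp.json` (`rate_hz`, `n_channels`,
#' `channel_ids`, `units`), and `session.yaml` (type, duration, arena side,
#' object positions). CSV numbers use shortest round-trip representation,
#' so timestamps survive a write/read cycle bit-identically.
#'
#' @param session A [session_record()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(
    tibble(unit_id = session$spikes$unit_id,
           timestamp_s = session$spikes$time),
    file.path(dir, "spikes.csv"))
  if (!is.null(session$trajectory)) {
    readr::write_csv(
      tibble(t_s = session$trajectory$time, x_cm = session$trajectory$x,
             y_cm = session$trajectory$y),
      file.path(dir, "tracking.csv"))
  }
  if (length(session$lfp) > 0) {
    rates <- vapply(session$lfp, function(ch) ch$rate, numeric(1))
    stopifnot(length(unique(rates)) == 1)
    mat <- do.call(rbind, lapply(session$lfp, function(ch) ch$samples))
    con <- file(file.path(dir, "lfp.bin"), "wb")
    writeBin(as.numeric(mat), con, size = 4, endian = "little")
    close(con)
    jsonlite::write_json(
      list(rate_hz = rates[[1]], n_channels = length(session$lfp),
           channel_ids = vapply(session$lfp, function(ch) ch$channel_id,
                                character(1)),
           units = "uV"),
      file.path(dir, "lfp.json"), auto_unbox = TRUE)
  }
  meta <- list(session_type = session$session_type,
               duration_s = session$duration,
               arena_side_cm = session$arena_side)
  if (nrow(session$objects) > 0) {
    meta$objects <- stats::setNames(
      lapply(seq_len(nrow(session$objects)),
             function(i) c(session$objects$x[i], session$objects$y[i])),
      session$objects$label)
  }
  yaml::write_yaml(meta, file.path(dir, "session.yaml"))
  invisible(dir)
}

#' Read a session directory
#'
#' Counterpart of [write_session()]; validates everything on the way in
#' (column presence, sorted timestamps, arena clamping with QC counts,
#' stream clock agreement).
#'
#' @param dir Session directory.
#' @return A [session_record()].
#' @export
read_session <- function(dir) {
  meta_path <- file.path(dir, "session.yaml")
  if (!file.exists(meta_path)) {
    abort(sprintf("No session.yaml in %s.", dir),
          class = "degumap_format_error")
  }
  meta <- yaml::read_yaml(meta_path)
  spikes_path <- file.path(dir, "spikes.csv")
  # base read.csv: C strtod parsing is correctly rounded, so timestamps
  # written with shortest round-trip digits read back bit-identically
  spikes <- if (file.exists(spikes_path)) {
    sp <- utils::read.csv(spikes_path)
    if (!all(c("unit_id", "timestamp_s") %in% names(sp))) {
      missing <- setdiff(c("unit_id", "timestamp_s"), names(sp))
      abort(sprintf("spikes.csv is missing column `%s`.", missing[1]),
            class = "degumap_format_error")
    }
    tibble(unit_id = as.character(sp$unit_id), time = sp$timestamp_s)
  } else NULL
  traj_path <- file.path(dir, "tracking.csv")
  traj <- if (file.exists(traj_path)) {
    as_trajectory(utils::read.csv(traj_path),
                  arena_side = meta$arena_side_cm %||% 90)
  } else NULL
  lfp <- list()
  side_path <- file.path(dir, "lfp.json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    con <- file(file.path(dir, "lfp.bin"), "rb")
    raw_n <- file.info(file.path(dir, "lfp.bin"))$size / 4
    vals <- readBin(con, "numeric", n = raw_n, size = 4, endian = "little")
    close(con)
    nch <- side$n_channels
    mat <- matrix(vals, nrow = nch)
    lfp <- lapply(seq_len(nch), function(i) {
      lfp_signal(mat[i, ], side$rate_hz, channel_id = side$channel_ids[i])
    })
    names(lfp) <- side$channel_ids
  }
  objects <- NULL
  if (!is.null(meta$objects)) {
    objects <- tibble(
      label = names(meta$objects),
      x = vapply(meta$objects, function(p) p[[1]], numeric(1)),
      y = vapply(meta$objects, function(p) p[[2]], numeric(1)))
  }
  session_record(meta$session_type, meta$duration_s, spikes = spikes,
                 trajectory = traj, lfp = lfp, objects = objects,
                 arena_side = meta$arena_side_cm %||% 90)
}
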