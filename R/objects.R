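#' Object-circle exploration time in consecutive windows
#'
#' Time spent with the tracked position inside a circle of `radius` cm
#' around each labeled object position, accumulated over consecutive
#' non-overlapping windows. Each tracking sample contributes its dwell time
#' (gaps excluded) to the circle containing it; circle membership includes
#' the boundary.
#'
#' @param traj Trajectory tibble.
#' @param layout Tibble with columns `label`, `x`, `y` (cm).
#' @param radius Circle radius in cm (10).
#' @param window Window length in seconds (30).
#' @return Tibble with `window`, `t_start`, `t_end`, `position`, `seconds`,
#'   `fraction` (of the window).
#' @export
exploration_time <- function(traj, layout, radius = 10, window = 30) {
  stopifnot(nrow(layout) > 0, radius > 0)
  wins <- window_segments(range(traj$time), window)
  dwell <- trajectory_dwell(traj)
  win_idx <- findInterval(traj$time, wins$t_start)
  in_any_win <- win_idx >= 1 & traj$time < max(wins$t_end)
  out <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    inside <- (traj$x - layout$x[i])^2 + (traj$y - layout$y[i])^2 <= radius^2
    sec <- tapply(dwell[inside & in_any_win],
                  factor(win_idx[inside & in_any_win],
                         levels = seq_len(nrow(wins))),
                  sum)
    sec <- ifelse(is.na(sec), 0, sec)
    out[[i]] <- dplyr::mutate(wins, position = layout$label[i],
                              seconds = as.numeric(sec),
                              fraction = pmin(as.numeric(sec) / window, 1))
  }
  bind_rows(out)
}

#' Normalize per-session firing rates by the day mean
#'
#' Each unit's per-session rate is divided by the unweighted mean of its
#' rates over the day's sessions, so every neuron contributes with equal
#' weight to population comparisons; by construction the mean of the
#' normalized rates across sessions is 1 for every unit. Units missing from
#' any session are excluded with a warning.
#'
#' @param rates Tibble with columns `unit_id`, `session`, `rate` (Hz); one
#'   row per unit and session.
#' @param object_sessions Character vector of session labels that contained
#'   objects (used to add the pooled `has_objects` grouping).
#' @return Tibble with `unit_id`, `session`, `rate`, `normalized`,
#'   `has_objects`.
#' @export
normalized_session_rates <- function(rates,
                                     object_sessions = c("sample", "test")) {
  n_sessions <- length(unique(rates$session))
  counts <- table(rates$unit_id)
  incomplete <- names(counts)[counts < n_sessions]
  if (length(incomplete) > 0) {
    warn(sprintf("%d unit(s) missing from some sessions excluded: %s",
                 length(incomplete), paste(incomplete, collapse = ", ")))
    rates <- rates[!rates$unit_id %in% incomplete, ]
  }
  rates |>
    group_by(.data$unit_id) |>
    mutate(normalized = .data$rate / mean(.data$rate)) |>
    ungroup() |>
    mutate(has_objects = .data$session %in% object_sessions)
}

#' Session rates from a list of session records
#'
#' @param sessions Named list of [session_record()]s; names are session
#'   labels.
#' @return Tibble `unit_id`, `session`, `n_spikes`, `duration`, `rate`.
#' @export
session_rates <- function(sessions) {
  out <- purrr::imap(sessions, function(s, label) {
    counts <- table(s$spikes$unit_id)
    tibble(unit_id = names(counts), session = label,
           n_spikes = as.integer(counts), duration = s$duration,
           rate = as.integer(counts) / s$duration)
  })
  bind_rows(out)
}

#' Firing rates inside object circles and in the rest of the maze
#'
#' Raw event counts and raw occupancy (no binning, no smoothing): the rate
#' inside the 10 cm circle around each object position, and in the
#' complement of the union of all circles. Regions with zero occupancy are
#' reported as `NA` (undefined), never as zero.
#'
#' @param spikes Numeric spike times for one unit.
#' @param traj Trajectory tibble.
#' @param layout Tibble `label`, `x`, `y`.
#' @param radius Circle radius (cm).
#' @param normalize_by Optional rate (Hz) to divide the regional rates by
#'   (e.g. the unit's day-mean rate).
#' @return Tibble with `region` (labels plus `"rest"`), `occupancy_s`,
#'   `n_spikes`, `rate`, and `normalized` when `normalize_by` is given.
#' @export
local_object_rates <- function(spikes, traj, layout, radius = 10,
                               normalize_by = NULL) {
  dwell <- trajectory_dwell(traj)
  idx <- findInterval(spikes, traj$time)
  ok <- idx >= 1
  idx <- idx[ok]
  in_circle <- matrix(FALSE, nrow(traj), nrow(layout))
  for (i in seq_len(nrow(layout))) {
    in_circle[, i] <- (traj$x - layout$x[i])^2 +
      (traj$y - layout$y[i])^2 <= radius^2
  }
  regions <- c(layout$label, "rest")
  rows <- vector("list", length(regions))
  in_rest <- rowSums(in_circle) == 0
  for (r in seq_along(regions)) {
    member <- if (regions[r] == "rest") in_rest else in_circle[, r]
    occ <- sum(dwell[member])
    nsp <- sum(member[idx])
    rate <- if (occ > 0) nsp / occ else NA_real_
    rows[[r]] <- tibble(region = regions[r], occupancy_s = occ,
                        n_spikes = nsp, rate = rate)
  }
  out <- bind_rows(rows)
  if (!is.null(normalize_by)) out$normalized <- out$rate / normalize_by
  out
}

#' Rank-based group comparisons in a tidy report
#'
#' Wraps the standard nonparametric tests: Wilcoxon signed-rank (paired) or
#' rank-sum (unpaired) for two groups, Kruskal-Wallis for more, and a
#' Tukey-Kramer-style post-hoc on rank-transformed data after a
#' Kruskal-Wallis test. The z statistic for Wilcoxon tests is recovered
#' from the two-sided p-value via the normal quantile, signed by the
#' direction of the group difference.
#'
#' @param data Data frame.
#' @param value,group Column names (strings) of the observation and group.
#' @param paired Logical; for two groups, use the signed-rank test on
#'   matched rows (data must be sorted consistently within group).
#' @param alternative Passed to [stats::wilcox.test()] for two groups.
#' @return List with `tests` (tibble: test, statistic_name, statistic, df,
#'   p_value) and `posthoc` (tibble of pairwise Tukey comparisons, or NULL).
#' @export
session_comparisons <- function(data, value, group, paired = FALSE,
                                alternative = "two.sided") {
  v <- data[[value]]
  g <- factor(data[[group]])
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  sizes <- table(g)
  if (any(sizes < 2)) {
    return(list(tests = tibble(test = "skipped",
                               statistic_name = NA_character_,
                               statistic = NA_real_, df = NA_real_,
                               p_value = NA_real_,
                               note = "group with fewer than 2 observations"),
                posthoc = NULL))
  }
  tests <- list()
  posthoc <- NULL
  if (nlevels(g) == 2) {
    lv <- levels(g)
    wt <- wilcox.test(v[g == lv[1]], v[g == lv[2]], paired = paired,
                      alternative = alternative, exact = FALSE)
    direction <- sign(median(v[g == lv[1]]) - median(v[g == lv[2]]))
    p2 <- if (alternative == "two.sided") wt$p.value else
      min(1, 2 * wt$p.value)
    z <- direction * abs(qnorm(pmax(p2 / 2, 1e-300)))
    tests$wilcoxon <- tibble(
      test = if (paired) "wilcoxon_signed_rank" else "wilcoxon_rank_sum",
      statistic_name = "z", statistic = z, df = NA_real_,
      p_value = wt$p.value)
  }
  if (nlevels(g) >= 3) {
    kw <- kruskal.test(v, g)
    tests$kruskal <- tibble(test = "kruskal_wallis", statistic_name = "H",
                            statistic = unname(kw$statistic),
                            df = unname(kw$parameter),
                            p_value = kw$p.value)
    tk <- TukeyHSD(aov(rank(v) ~ g))$g
    posthoc <- tibble(comparison = rownames(tk), diff_rank = tk[, "diff"],
                      p_adj = tk[, "p adj"])
  }
  list(tests = bind_rows(tests), posthoc = posthoc)
}
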