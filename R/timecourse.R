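# Relative-day alignment and cohort time courses.
#
# Each user's first calendar day with at least one puff is their relative
# day 1, so users enrolling on different dates are aligned by experience
# with the device, not by calendar. Cohort daily means average over the
# users *active* on each relative day — a user contributes one value per
# metric per day regardless of how many puffs they took, and inactive
# days are absent, not zero-filled. This is the aggregation under which
# the adaptation pattern (low day 1, short ramp, stable plateau) is
# defined.

#' Per-user, per-active-day summaries
#'
#' One row per (user, calendar day with >= 1 puff): puff count, mean puff
#' duration, total estimated nicotine over estimable puffs, and the count
#' of estimable puffs. Relative day 1 is the user's first active day;
#' inactive days leave gaps rather than zero rows. Puff counts are
#' conserved: the summaries' `puff_count` sums to the number of input
#' puffs.
#'
#' @param puffs tibble of puff records carrying an `emission_mg` column
#'   (see [add_puff_emissions()]); if absent, nicotine totals are NA.
#' @return tibble of daily user summaries: `device_id`, `relative_day`,
#'   `calendar_date`, `puff_count`, `mean_duration_s`,
#'   `total_nicotine_mg`, `estimable_puffs`.
#' @export
summarize_user_days <- function(puffs) {
  if (!"emission_mg" %in% names(puffs)) puffs$emission_mg <- NA_real_
  puffs |>
    dplyr::mutate(calendar_date = as.Date(.data$timestamp)) |>
    dplyr::group_by(.data$device_id, .data$calendar_date) |>
    dplyr::summarise(
      puff_count = dplyr::n(),
      mean_duration_s = mean(.data$duration_s),
      total_nicotine_mg = sum(.data$emission_mg, na.rm = TRUE),
      estimable_puffs = sum(!is.na(.data$emission_mg)),
      .groups = "drop_last"
    ) |>
    dplyr::mutate(
      relative_day = as.integer(.data$calendar_date - min(.data$calendar_date)) + 1L
    ) |>
    dplyr::ungroup() |>
    dplyr::select("device_id", "relative_day", "calendar_date", "puff_count",
                  "mean_duration_s", "total_nicotine_mg", "estimable_puffs") |>
    dplyr::arrange(.data$device_id, .data$relative_day)
}

#' Cohort-level time series over relative days
#'
#' For each relative day, the unweighted mean and SE across active users
#' of daily puff count, daily mean puff duration and daily nicotine
#' consumption. Each active user contributes one value per metric (their
#' own daily mean duration, not a puff-weighted pool), so heavy users do
#' not dominate the duration curve. SE = SD / sqrt(n_active), undefined
#' for days with a single active user.
#'
#' @param summaries tibble from [summarize_user_days()].
#' @return tibble with one row per relative day: `relative_day`,
#'   `n_active`, then `puffs_mean`, `puffs_se`, `duration_mean`,
#'   `duration_se`, `nicotine_mean`, `nicotine_se`.
#' @export
cohort_series <- function(summaries) {
  se_of <- function(x) {
    if (length(x) < 2) NA_real_ else stats::sd(x) / sqrt(length(x))
  }
  summaries |>
    dplyr::group_by(.data$relative_day) |>
    dplyr::summarise(
      n_active = dplyr::n(),
      puffs_mean = mean(.data$puff_count),
      puffs_se = se_of(.data$puff_count),
      duration_mean = mean(.data$mean_duration_s),
      duration_se = se_of(.data$mean_duration_s),
      nicotine_mean = mean(.data$total_nicotine_mg),
      nicotine_se = se_of(.data$total_nicotine_mg),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$relative_day)
}

#' Adaptation metrics for a cohort time series
#'
#' Quantifies the day-1-low / ramp / plateau pattern for one metric:
#' the day-1 mean; the plateau mean over a stated window (default
#' relative days 8-21, i.e. after the first week); `ramp_days`, the first
#' relative day whose mean is within `tolerance * plateau_mean` of the
#' plateau; and the least-squares slope (with SE) of the daily means over
#' the plateau window, a slope consistent with zero indicating stable use
#' with no escalation.
#'
#' @param series tibble from [cohort_series()].
#' @param metric one of `"puffs"`, `"duration"`, `"nicotine"`.
#' @param plateau_window length-2 integer range of relative days.
#' @param tolerance fraction of the plateau mean defining "arrived".
#' @return list: `metric`, `day1_mean`, `plateau_mean`, `ramp_days`,
#'   `plateau_slope`, `plateau_slope_se`, `plateau_window`, `tolerance`.
#' @export
#' @examples
#' # step series: 120 on day 1, 250 after
#' s <- tibble::tibble(device_id = "u", relative_day = 1:21,
#'                     calendar_date = as.Date("2022-03-01") + 0:20,
#'                     puff_count = c(120, rep(250, 20)),
#'                     mean_duration_s = 3, total_nicotine_mg = 1,
#'                     estimable_puffs = 1)
#' adaptation_metrics(cohort_series(s), tolerance = 0.1)$ramp_days # 2
adaptation_metrics <- function(series, metric = c("puffs", "duration", "nicotine"),
                               plateau_window = c(8, 21), tolerance = 0.1) {
  metric <- match.arg(metric)
  mcol <- paste0(metric, "_mean")
  days <- series$relative_day
  if (plateau_window[1] > plateau_window[2] ||
      !any(days >= plateau_window[1] & days <= plateau_window[2])) {
    abort_pufftopo("plateau window lies outside the observed relative days",
                   "pufftopo_config_error")
  }
  in_window <- days >= plateau_window[1] & days <= plateau_window[2]
  m <- series[[mcol]]
  plateau_mean <- mean(m[in_window])
  day1_mean <- if (1 %in% days) m[days == 1] else NA_real_
  hit <- abs(m - plateau_mean) <= tolerance * abs(plateau_mean)
  ramp_days <- if (any(hit)) min(days[hit]) else NA_integer_
  fit <- stats::lm(y ~ d, data = data.frame(y = m[in_window], d = days[in_window]))
  # a perfectly flat window is a legitimate input, not a modelling worry
  co <- suppressWarnings(summary(fit))$coefficients
  slope <- unname(co["d", "Estimate"])
  slope_se <- if (nrow(co) >= 2 && sum(in_window) > 2) {
    unname(co["d", "Std. Error"])
  } else {
    NA_real_
  }
  list(metric = metric, day1_mean = day1_mean, plateau_mean = plateau_mean,
       ramp_days = ramp_days, plateau_slope = slope,
       plateau_slope_se = slope_se, plateau_window = plateau_window,
       tolerance = tolerance)
}

#' Split users by total use span and recompute cohort series
#'
#' Users are partitioned by the whole-week span of their active use
#' (last active relative day, rounded up to weeks) — the robustness view
#' in which the adaptation pattern is checked within each use-duration
#' subgroup. The partition over users is exhaustive and disjoint; empty
#' subgroups are omitted with a notice.
#'
#' @param summaries tibble from [summarize_user_days()].
#' @param week_days days per week bin (7).
#' @return named list of [cohort_series()] tibbles, names `"1"`, `"2"`,
#'   ... weeks, with a `membership` attribute (tibble `device_id`,
#'   `span_days`, `weeks`).
#' @export
subgroup_by_duration <- function(summaries, week_days = 7) {
  membership <- summaries |>
    dplyr::group_by(.data$device_id) |>
    dplyr::summarise(span_days = max(.data$relative_day), .groups = "drop") |>
    dplyr::mutate(weeks = ceiling(.data$span_days / week_days))
  out <- lapply(split(membership$device_id, membership$weeks), function(ids) {
    cohort_series(summaries[summaries$device_id %in% ids, , drop = FALSE])
  })
  structure(out, membership = membership)
}

#' Plot a cohort time series with its SE band
#'
#' Mean line and mean +/- SE ribbon over relative days for one metric.
#'
#' @param series tibble from [cohort_series()].
#' @param metric one of `"puffs"`, `"duration"`, `"nicotine"`.
#' @return a ggplot object.
#' @export
plot_cohort_series <- function(series, metric = c("puffs", "duration", "nicotine")) {
  metric <- match.arg(metric)
  mcol <- paste0(metric, "_mean")
  scol <- paste0(metric, "_se")
  ylab <- switch(metric, puffs = "Puffs per day",
                 duration = "Puff duration per day (s)",
                 nicotine = "Nicotine consumption per day (mg)")
  ggplot2::ggplot(series, ggplot2::aes(x = .data$relative_day, y = .data[[mcol]])) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data[[mcol]] - .data[[scol]],
                   ymax = .data[[mcol]] + .data[[scol]]),
      fill = "steelblue", alpha = 0.3
    ) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "Relative day", y = ylab) +
    ggplot2::theme_minimal()
}
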