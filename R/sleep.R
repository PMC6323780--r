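#' Score sleep by the five-minute inactivity rule
#'
#' Fly sleep is defined as five or more consecutive minutes without a beam
#' break. Every maximal run of zero-count minutes of length >= 5 is a sleep
#' bout and all of its minutes are scored asleep. When a lifespan is
#' supplied, scoring stops at death: minutes after `lifespan_minutes` are
#' neither sleep nor wake (NA), so dead flies do not inflate sleep.
#'
#' @param series A dense, ghost-filtered [beam_series()].
#' @param lifespan_minutes Optional death minute (offset from origin) at
#'   which to truncate scoring.
#' @param min_bout Minimum inactive run length counting as sleep (minutes).
#' @return A `sleep_series`: list with `fly_id`, `asleep` (logical per
#'   minute, NA after death) and `bouts` (tibble `start_minute` 0-based,
#'   `length`).
#' @export
score_sleep <- function(series, lifespan_minutes = NULL, min_bout = 5L) {
  counts <- series$counts
  n_alive <- if (is.null(lifespan_minutes)) length(counts) else
    min(length(counts), as.integer(lifespan_minutes) + 1L)
  asleep <- rep(NA, length(counts))
  if (n_alive > 0) {
    zero <- counts[seq_len(n_alive)] == 0L
    r <- rle(zero)
    is_bout <- r$values & r$lengths >= min_bout
    asleep[seq_len(n_alive)] <- inverse.rle(list(values = is_bout, lengths = r$lengths))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths          # 0-based start offsets
    bouts <- tibble(start_minute = starts[is_bout], length = r$lengths[is_bout])
  } else {
    bouts <- tibble(start_minute = integer(0), length = integer(0))
  }
  structure(list(fly_id = series$fly_id, asleep = asleep, bouts = bouts),
            class = "sleep_series")
}

week_window <- function(week) {
  c((week - 1L) * MINUTES_PER_WEEK, week * MINUTES_PER_WEEK)   # [start, end)
}

survived_week <- function(lifespan_minutes, week) {
  lifespan_minutes >= week * MINUTES_PER_WEEK - 1L
}

#' Weekly sleep summary for one fly
#'
#' Sleep amount in mean minutes of sleep per hour over a 168-h week. Only
#' flies that survived through the entire week are included; for the rest
#' the value is NA and `included` is FALSE.
#'
#' @param series Ghost-filtered [beam_series()].
#' @param week Week index (1-based; week k covers hours
#'   \[168 (k-1), 168 k) from the series origin).
#' @param lifespan_minutes Death minute from [call_death()].
#' @return One-row tibble: `fly_id`, `week`, `included`, `sleep_min_per_hr`.
#' @export
weekly_sleep_summary <- function(series, week, lifespan_minutes) {
  w <- week_window(week)
  if (w[2] > length(series$counts)) abort("week extends beyond the recorded span")
  if (!survived_week(lifespan_minutes, week)) {
    return(tibble(fly_id = series$fly_id, week = week, included = FALSE,
                  sleep_min_per_hr = NA_real_))
  }
  ss <- score_sleep(series, lifespan_minutes)
  asleep <- ss$asleep[(w[1] + 1):w[2]]
  tibble(fly_id = series$fly_id, week = week, included = TRUE,
         sleep_min_per_hr = sum(asleep, na.rm = TRUE) / 168)
}

#' Weekly activity summary for one fly
#'
#' Activity in mean beam breaks per minute over a 168-h week, with the same
#' week-survivor inclusion rule as [weekly_sleep_summary()].
#'
#' @inheritParams weekly_sleep_summary
#' @return One-row tibble: `fly_id`, `week`, `included`,
#'   `activity_per_min`.
#' @export
weekly_activity_summary <- function(series, week, lifespan_minutes) {
  w <- week_window(week)
  if (w[2] > length(series$counts)) abort("week extends beyond the recorded span")
  if (!survived_week(lifespan_minutes, week)) {
    return(tibble(fly_id = series$fly_id, week = week, included = FALSE,
                  activity_per_min = NA_real_))
  }
  tibble(fly_id = series$fly_id, week = week, included = TRUE,
         activity_per_min = sum(series$counts[(w[1] + 1):w[2]]) / MINUTES_PER_WEEK)
}

#' Full-life sleep and activity summary
#'
#' Metrics over the whole life excluding the last three days (flies show
#' reduced activity near death, which would blur sleep into moribund
#' inactivity). Flies living 72 h or less are flagged and excluded.
#'
#' @inheritParams weekly_sleep_summary
#' @return One-row tibble: `fly_id`, `included`, `sleep_min_per_hr`,
#'   `activity_per_min`.
#' @export
fulllife_summary <- function(series, lifespan_minutes) {
  cutoff <- lifespan_minutes - 3L * MINUTES_PER_DAY     # [0, lifespan - 4320)
  if (cutoff <= 0) {
    return(tibble(fly_id = series$fly_id, included = FALSE,
                  sleep_min_per_hr = NA_real_, activity_per_min = NA_real_))
  }
  ss <- score_sleep(series, lifespan_minutes)
  idx <- seq_len(cutoff)
  tibble(fly_id = series$fly_id, included = TRUE,
         sleep_min_per_hr = sum(ss$asleep[idx], na.rm = TRUE) / (cutoff / 60),
         activity_per_min = sum(series$counts[idx]) / cutoff)
}

#' Weekly summaries for a whole cohort
#'
#' @param cohort A `ccm_cohort`.
#' @param weeks Week indices to summarise.
#' @return Tibble with one row per fly x week: metadata, `included`,
#'   `sleep_min_per_hr`, `activity_per_min`.
#' @export
cohort_weekly_summaries <- function(cohort, weeks = 1:3) {
  life <- cohort_lifespans(cohort)
  filtered <- purrr::map(cohort$series[!cohort$excluded],
                         function(s) filter_ghosts(s)$series)
  purrr::map_dfr(weeks, function(wk) {
    rows <- purrr::map2_dfr(filtered, life$lifespan_minutes, function(s, lm) {
      dplyr::inner_join(weekly_sleep_summary(s, wk, lm),
                        weekly_activity_summary(s, wk, lm),
                        by = c("fly_id", "week", "included"))
    })
    dplyr::left_join(rows, life[, c("fly_id", "sex", "treatment")], by = "fly_id")
  })
}

# vectorised ZT (hours) of minute offsets from `origin`, assuming each
# minute falls in a single LD epoch; NA outside LD epochs
zt_minutes <- function(schedule, origin, minute_offsets) {
  stamps <- as.numeric(origin) + minute_offsets * 60
  zt <- rep(NA_real_, length(stamps))
  for (i in seq_len(nrow(schedule))) {
    if (schedule$mode[i] != "LD") next
    sel <- stamps >= as.numeric(schedule$start[i]) & stamps < as.numeric(schedule$end[i])
    zt[sel] <- ((stamps[sel] - as.numeric(schedule$start[i])) / 3600) %% schedule$period_h[i]
  }
  zt
}

profile_week_survivors <- function(cohort, week) {
  life <- cohort_lifespans(cohort)
  keep <- life$fly_id[survived_week(life$lifespan_minutes, week)]
  cohort[!cohort$excluded & cohort$fly_id %in% keep, ]
}

profile_by_group <- function(cohort, week, bin_minutes, per_fly_fun) {
  schedules <- cohort_schedules(cohort)
  surv <- profile_week_survivors(cohort, week)
  purrr::map_dfr(unique(surv$treatment), function(grp) {
    sched <- schedules[[if (grp == "CCM") "CCM" else "control"]]
    t_h <- sched$period_h[which(sched$mode == "LD")[1]]
    n_cycles <- full_cycles_in(sched, 168)
    w0 <- week_window(week)[1]
    # restrict to the week's complete cycles (6 x 28 h or 7 x 24 h = 168 h)
    offs <- w0 + seq_len(n_cycles * t_h * 60) - 1
    zt <- zt_minutes(sched, surv$series[[1]]$origin, offs)
    bin <- floor(zt * 60 / bin_minutes)
    n_bins <- as.integer(round(t_h * 60 / bin_minutes))
    rows <- surv[surv$treatment == grp, ]
    per_fly <- purrr::map(seq_len(nrow(rows)), function(k) {
      per_fly_fun(rows$series[[k]], offs, bin, n_bins, n_cycles, bin_minutes)
    })
    mat <- do.call(rbind, per_fly)
    tibble(
      treatment = grp, week = week,
      zt_bin = (seq_len(n_bins) - 1) * bin_minutes / 60,
      mean = colMeans(mat),
      sem = apply(mat, 2, function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else 0),
      n = nrow(mat)
    )
  })
}

#' ZT-binned activity profile
#'
#' Per fly, beam breaks per minute are averaged within each `bin_minutes`
#' zeitgeber-time bin across the week's complete cycles (seven 24-h cycles
#' for controls, six 28-h cycles for misaligned flies), then averaged with
#' SEM across flies. Only flies surviving the whole week contribute.
#'
#' @param cohort A `ccm_cohort`.
#' @param week Week index.
#' @param bin_minutes Bin width (default 30 min; 2T bins per cycle).
#' @return Tibble `treatment`, `week`, `zt_bin` (h), `mean` (counts/min),
#'   `sem`, `n`.
#' @export
activity_profile <- function(cohort, week, bin_minutes = 30) {
  profile_by_group(cohort, week, bin_minutes,
    function(series, offs, bin, n_bins, n_cycles, bw) {
      x <- series$counts[offs + 1]
      vapply(seq_len(n_bins) - 1L, function(b) mean(x[bin == b]), numeric(1))
    })
}

#' ZT-binned sleep profile
#'
#' Mean minutes of sleep per `bin_minutes` bin (0-30 for 30-min bins) over
#' a single light-dark cycle, averaged across the week's complete cycles
#' per fly and then across flies.
#'
#' @inheritParams activity_profile
#' @return Tibble `treatment`, `week`, `zt_bin` (h), `mean` (min sleep per
#'   bin), `sem`, `n`.
#' @export
sleep_profile <- function(cohort, week, bin_minutes = 30) {
  profile_by_group(cohort, week, bin_minutes,
    function(series, offs, bin, n_bins, n_cycles, bw) {
      asleep <- score_sleep(series)$asleep[offs + 1]
      vapply(seq_len(n_bins) - 1L, function(b) sum(asleep[bin == b]) / n_cycles,
             numeric(1))
    })
}

#' Mean normalized activity across flies (actogram input)
#'
#' Each fly's minute counts over the window are divided by that fly's
#' window-mean activity (so every fly carries equal weight regardless of
#' overall vigor), averaged across flies, and laid out in 24-h rows for
#' single-plotted actograms. Flies with zero mean activity in the window
#' are excluded with a warning.
#'
#' @param cohort A `ccm_cohort`.
#' @param window_minutes `c(start, end)` minute offsets (0-based, half-open)
#'   from the series origin, e.g. covering the last 3 LD and first 3 DD
#'   days.
#' @param group Treatment group to plot (default all flies together).
#' @return Tibble `line` (24-h row, 1-based), `minute_of_line` (0-1439),
#'   `mean_norm_activity`.
#' @export
normalized_actogram <- function(cohort, window_minutes, group = NULL) {
  rows <- cohort[!cohort$excluded, ]
  if (!is.null(group)) rows <- rows[rows$treatment == group, ]
  idx <- (window_minutes[1] + 1):window_minutes[2]
  mat <- do.call(rbind, purrr::map(rows$series, function(s) {
    x <- s$counts[idx]
    m <- mean(x)
    if (m == 0) NULL else x / m
  }))
  dropped <- nrow(rows) - NROW(mat)
  if (dropped > 0) warn(sprintf("%d fly/flies with zero mean activity excluded", dropped))
  if (is.null(mat)) abort("no flies with nonzero activity in window")
  avg <- colMeans(mat)
  n <- length(avg)
  tibble(
    line = (seq_len(n) - 1) %/% MINUTES_PER_DAY + 1L,
    minute_of_line = (seq_len(n) - 1) %% MINUTES_PER_DAY,
    mean_norm_activity = avg
  )
}

#' Sleep-longevity rank correlation
#'
#' Spearman correlation between early-life sleep and lifespan, with a
#' Fisher-z 95% confidence interval.
#'
#' @param data Data frame with one row per fly.
#' @param sleep,lifespan Columns (tidy-eval): sleep (min/hr) and lifespan
#'   (days).
#' @return Tibble `rho`, `conf.low`, `conf.high`, `p.value`, `n`.
#' @export
correlate_sleep_longevity <- function(data, sleep = sleep_min_per_hr,
                                      lifespan = lifespan_days) {
  x <- dplyr::pull(data, {{ sleep }})
  y <- dplyr::pull(data, {{ lifespan }})
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) abort("need at least 4 flies with both sleep and lifespan")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    abort("constant input vector: ranks are degenerate")
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  rho <- unname(ct$estimate)
  z <- atanh(rho)
  se <- 1 / sqrt(length(x) - 3)
  tibble(rho = rho,
         conf.low = tanh(z - qnorm(0.975) * se),
         conf.high = tanh(z + qnorm(0.975) * se),
         p.value = ct$p.value,
         n = length(x))
}
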