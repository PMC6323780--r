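#' Remove isolated post-mortem "ghost" readings
#'
#' The DAM system occasionally registers single beam breaks long after a
#' fly's last real activity. A nonzero bin is treated as a ghost iff it is
#' isolated on both sides: the nearest preceding *retained* nonzero bin is
#' more than 12 h (720 min) earlier, and the nearest following nonzero bin
#' is more than 12 h later or absent. The scan runs left to right against
#' retained activity, so a cluster of late counts (not isolated) is kept.
#' A series' very first activity is never a ghost.
#'
#' @param series A [beam_series()].
#' @return List with `series` (ghosts zeroed) and `ghost_minutes`
#'   (0-based minute offsets of removed bins).
#' @export
filter_ghosts <- function(series) {
  counts <- series$counts
  nz <- which(counts > 0L)          # 1-based bin indices
  ghosts <- integer(0)
  last_retained <- NA_integer_
  for (k in seq_along(nz)) {
    i <- nz[k]
    if (!is.na(last_retained) && (i - last_retained) > 720L) {
      nxt <- if (k < length(nz)) nz[k + 1L] else NA_integer_
      if (is.na(nxt) || (nxt - i) > 720L) {
        ghosts <- c(ghosts, i)
        next                          # ghost: not retained
      }
    }
    last_retained <- i
  }
  if (length(ghosts) > 0) counts[ghosts] <- 0L
  out <- series
  out$counts <- counts
  list(series = out, ghost_minutes = ghosts - 1L)
}

#' Call death from the last beam break
#'
#' Longevity is the last minute at which a (ghost-filtered) beam break
#' occurred, counted from the series origin.
#'
#' @param series A ghost-filtered [beam_series()] with at least one
#'   nonzero bin.
#' @param ghost_minutes Optional minute offsets removed by
#'   [filter_ghosts()], carried into the record.
#' @return One-row tibble: `fly_id`, `lifespan_minutes` (minutes since
#'   origin), `lifespan_days`, `event` (TRUE), `n_ghosts`.
#' @export
call_death <- function(series, ghost_minutes = integer(0)) {
  nz <- which(series$counts > 0L)
  if (length(nz) == 0) abort("all-zero series: no evidence of life")
  lifespan <- max(nz) - 1L
  tibble(fly_id = series$fly_id,
         lifespan_minutes = lifespan,
         lifespan_days = lifespan / MINUTES_PER_DAY,
         event = TRUE,
         n_ghosts = length(ghost_minutes))
}

#' Lifespan table for a cohort
#'
#' Applies [filter_ghosts()] then [call_death()] to every non-excluded fly.
#'
#' @param cohort A `ccm_cohort` (or any tibble with `fly_id`, `sex`,
#'   `treatment`, `excluded` and a `series` list-column).
#' @return Tibble with one row per fly: metadata plus lifespan columns.
#' @export
cohort_lifespans <- function(cohort) {
  keep <- !cohort$excluded
  rows <- purrr::map(which(keep), function(i) {
    fg <- filter_ghosts(cohort$series[[i]])
    call_death(fg$series, fg$ghost_minutes)
  })
  dplyr::bind_cols(
    cohort[keep, c("fly_id", "sex", "treatment")],
    dplyr::bind_rows(rows)[, c("lifespan_minutes", "lifespan_days", "event",
                               "n_ghosts")]
  )
}

#' Kaplan-Meier survival fit
#'
#' Product-limit estimator with Greenwood variance and log-log 95%
#' confidence intervals; the median is the smallest time with survival
#' at or below 0.5.
#'
#' @param data Data frame of lifespans.
#' @param time,event Columns (tidy-eval) holding the survival time and the
#'   event indicator; `event` defaults to all-events if absent.
#' @return A `km_fit` object wrapping [survival::survfit()]; see
#'   [tidy.km_fit()] and [glance.km_fit()].
#' @export
km_fit <- function(data, time = lifespan_days, event = NULL) {
  t <- dplyr::pull(data, {{ time }})
  e <- pull_event(data, rlang::enquo(event), length(t))
  if (length(t) < 1) abort("need at least one observation")
  fit <- survival::survfit(survival::Surv(t, e) ~ 1, conf.type = "log-log")
  structure(list(fit = fit, n = length(t)), class = "km_fit")
}

#' Two-group log-rank test
#'
#' @param data Data frame with one row per fly.
#' @param time,group,event Columns (tidy-eval): survival time, two-level
#'   group, and optional event indicator (defaults to all events).
#' @return Tibble `statistic` (chi-square, 1 df), `df`, `p.value`.
#' @export
logrank_test <- function(data, time = lifespan_days, group = treatment,
                         event = NULL) {
  t <- dplyr::pull(data, {{ time }})
  g <- dplyr::pull(data, {{ group }})
  e <- pull_event(data, rlang::enquo(event), length(t))
  if (length(unique(g)) != 2 || any(table(g) == 0)) {
    abort("log-rank test needs two non-empty groups")
  }
  sd <- survival::survdiff(survival::Surv(t, e) ~ g)
  tibble(statistic = sd$chisq, df = 1L,
         p.value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Maximises the partial likelihood with Efron tie handling (lifespans at
#' day resolution are heavily tied). Hazard ratios are `exp(coef)` with
#' Wald 95% confidence intervals. A Schoenfeld-residual test
#' ([survival::cox.zph()]) is attached as a proportionality flag.
#'
#' @param data Data frame, one row per fly.
#' @param covariates Character vector of covariate column names (one =
#'   univariate model, several = multivariate).
#' @param time,event Columns (tidy-eval) for survival time and optional
#'   event indicator.
#' @return A `hazard_model`; see [tidy.hazard_model()] and
#'   [glance.hazard_model()].
#' @export
cox_fit <- function(data, covariates, time = lifespan_days, event = NULL) {
  t <- dplyr::pull(data, {{ time }})
  e <- pull_event(data, rlang::enquo(event), length(t))
  if (sum(e) < 1) abort("need at least one event")
  for (cv in covariates) {
    if (!cv %in% names(data)) abort(sprintf("covariate '%s' not in data", cv))
    if (dplyr::n_distinct(data[[cv]]) < 2) {
      abort(sprintf("covariate '%s' is constant: hazard ratio not identifiable", cv))
    }
  }
  df <- data[, covariates, drop = FALSE]
  df$.time <- t
  df$.event <- e
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~", paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  if (!is.null(fit$info) || any(is.na(stats::coef(fit)))) {
    abort("Cox model did not converge to identifiable coefficients")
  }
  zph <- tryCatch(survival::cox.zph(fit), error = function(...) NULL)
  structure(
    list(fit = fit,
         type = if (length(covariates) > 1) "multivariate" else "univariate",
         covariates = covariates,
         ph_test = zph),
    class = "hazard_model"
  )
}

#' Sleep-matched control/CCM pairing
#'
#' Without-replacement matching of control to misaligned flies with similar
#' weekly sleep (within `tolerance` min/hr). Controls are processed in
#' ascending sleep order and each is paired with the unmatched CCM fly of
#' lowest sleep value within tolerance (ties broken by fly id). This
#' leftmost-feasible greedy attains the maximum possible number of pairs
#' for interval-tolerance matching on a line; unmatched flies are dropped.
#'
#' @param control_sleep,ccm_sleep Data frames with columns `fly_id` and
#'   `sleep` (min/hr), one row per fly.
#' @param tolerance Maximum |sleep difference| allowed in a pair, min/hr.
#' @return Tibble of pairs: `control_id`, `ccm_id`, `control_sleep`,
#'   `ccm_sleep`, `sleep_diff`.
#' @export
sleep_match <- function(control_sleep, ccm_sleep, tolerance = 0.5) {
  if (tolerance <= 0) abort("tolerance must be > 0")
  ctl <- dplyr::arrange(as_tibble(control_sleep), .data$sleep, .data$fly_id)
  ccm <- dplyr::arrange(as_tibble(ccm_sleep), .data$sleep, .data$fly_id)
  taken <- rep(FALSE, nrow(ccm))
  pairs <- vector("list", nrow(ctl))
  for (i in seq_len(nrow(ctl))) {
    ok <- which(!taken &
                  ccm$sleep >= ctl$sleep[i] - tolerance &
                  ccm$sleep <= ctl$sleep[i] + tolerance)
    if (length(ok) == 0) next
    j <- ok[1]                      # lowest sleep, then fly_id (pre-sorted)
    taken[j] <- TRUE
    pairs[[i]] <- tibble(control_id = ctl$fly_id[i], ccm_id = ccm$fly_id[j],
                         control_sleep = ctl$sleep[i], ccm_sleep = ccm$sleep[j],
                         sleep_diff = ccm$sleep[j] - ctl$sleep[i])
  }
  out <- dplyr::bind_rows(pairs)
  if (nrow(out) == 0) {
    out <- tibble(control_id = character(0), ccm_id = character(0),
                  control_sleep = numeric(0), ccm_sleep = numeric(0),
                  sleep_diff = numeric(0))
  }
  out
}

#' Percent reduction in median lifespan
#'
#' `100 * (control - treated) / control`, rounded half-up to one decimal —
#' the headline effect size of a misalignment longevity experiment.
#'
#' @param ctrl_median_days,ccm_median_days Median lifespans in days.
#' @return Percent reduction, one decimal.
#' @export
percent_median_reduction <- function(ctrl_median_days, ccm_median_days) {
  if (ctrl_median_days <= 0) abort("control median must be positive")
  round_half_up(100 * (ctrl_median_days - ccm_median_days) / ctrl_median_days, 1)
}

#' Hazard ratio as a signed percent change in risk
#'
#' A hazard ratio of 1.94 reads as "94% more likely to die at any point in
#' time"; 0.74 as "26% less likely".
#'
#' @param hr Hazard ratio (> 0).
#' @return Signed integer percent, `100 * (hr - 1)` rounded half-up.
#' @export
hazard_percent <- function(hr) {
  if (hr <= 0) abort("hazard ratio must be positive")
  p <- 100 * (hr - 1)
  as.integer(sign(p) * round_half_up(abs(p), 0))
}

#' Sleep-hours equivalent of a treatment hazard ratio
#'
#' Given a protective per-hour-of-sleep hazard ratio `hr_sleep_per_hour`,
#' the treatment effect `hr_treatment` equals the risk increase of losing
#' `h = log(hr_treatment) / (-log(hr_sleep_per_hour))` hours of daily
#' sleep.
#'
#' @param hr_treatment Treatment hazard ratio (>= 1).
#' @param hr_sleep_per_hour Per-hour-of-sleep hazard ratio, in (0, 1).
#' @return Equivalent hours of sleep lost, one decimal.
#' @export
equivalent_sleep_loss <- function(hr_treatment, hr_sleep_per_hour) {
  if (hr_sleep_per_hour >= 1 || hr_sleep_per_hour <= 0) {
    abort("hr_sleep_per_hour must be in (0, 1): sleep must be protective")
  }
  if (hr_treatment < 1) abort("hr_treatment must be >= 1")
  round_half_up(log(hr_treatment) / (-log(hr_sleep_per_hour)), 1)
}

pull_event <- function(data, quo, n) {
  if (rlang::quo_is_null(quo)) rep(TRUE, n) else dplyr::pull(data, !!quo)
}
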