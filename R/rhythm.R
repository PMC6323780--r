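#' Chi-squared periodogram (Sokolove-Bushell)
#'
#' For each candidate period P (in 1-min steps) the N-bin series is folded
#' into P columns; with column means `M_h`, grand mean `M`, K = N / P rows
#' per column and overall variance `s2 = sum_i (x_i - M)^2 / N`, the
#' statistic is
#'
#'   Q(P) = K * sum_h (M_h - M)^2 / s2
#'
#' which under the null of no rhythm is approximately chi-squared with
#' P - 1 degrees of freedom (each column mean has variance s2 / K). The significance line is the chi-squared
#' quantile at 1 - alpha; rhythm power is Q at the dominant period minus
#' that line (a fly is called rhythmic iff power > 0). The dominant period
#' is the argmax of Q relative to the significance line (smallest P on
#' ties) — relative, because the null level of Q grows like P - 1, which
#' would otherwise tilt the argmax toward the long end of wide search
#' ranges — and it is reported even when below the line. An incomplete
#' final fold column is averaged over however many rows cover it.
#'
#' @param series A [beam_series()] or a numeric count vector (1-min bins).
#' @param period_range_min `c(min, max)` trial periods in minutes.
#' @param alpha Significance level for the chi-squared line (default 0.01).
#' @return A `ccm_periodogram`: tibble `period`, `q`, `sig` with attributes
#'   `dominant_period`, `power`, `rhythmic`, `alpha`, `n`.
#' @export
chi2_periodogram <- function(series, period_range_min = c(960, 2160),
                             alpha = 0.01) {
  x <- if (inherits(series, "beam_series")) as.numeric(series$counts) else as.numeric(series)
  n <- length(x)
  periods <- seq(as.integer(period_range_min[1]), as.integer(period_range_min[2]))
  if (n < 2 * max(periods)) {
    abort(sprintf("series too short (%d bins) for max period %d min: need >= 2 cycles",
                  n, max(periods)))
  }
  xbar <- mean(x)
  denom <- sum((x - xbar)^2)
  if (denom == 0) abort("zero-variance series: periodogram undefined")
  q <- vapply(periods, function(p) {
    pad <- ceiling(n / p) * p - n
    m <- matrix(c(x, rep(NA_real_, pad)), nrow = p)
    col_means <- rowMeans(m, na.rm = TRUE)
    (n / p) * sum((col_means - xbar)^2) / (denom / n)
  }, numeric(1))
  sig <- qchisq(1 - alpha, df = periods - 1)
  dom_i <- which.max(q - sig)                 # first max = smallest P on ties
  power <- q[dom_i] - sig[dom_i]
  out <- tibble(period = periods, q = q, sig = sig)
  attr(out, "dominant_period") <- periods[dom_i]
  attr(out, "power") <- power
  attr(out, "rhythmic") <- power > 0
  attr(out, "alpha") <- alpha
  attr(out, "n") <- n
  class(out) <- c("ccm_periodogram", class(out))
  out
}

#' @export
print.ccm_periodogram <- function(x, ...) {
  cat(sprintf(
    "<chi2 periodogram> dominant period %d min (%.2f h), power %.1f, %s\n",
    attr(x, "dominant_period"), attr(x, "dominant_period") / 60,
    attr(x, "power"), if (attr(x, "rhythmic")) "rhythmic" else "arrhythmic"))
  NextMethod()
}

#' Dominant period / rhythm power accessors
#' @param pg A `ccm_periodogram`.
#' @return Dominant period in minutes; rhythm power (Q minus the
#'   significance line at the dominant period).
#' @export
dominant_period <- function(pg) attr(pg, "dominant_period")

#' @rdname dominant_period
#' @export
rhythm_power <- function(pg) attr(pg, "power")

#' Weekly LD rhythmicity of one fly
#'
#' Periodogram over one 168-h week of entrained data. The default search
#' range (16-36 h) brackets both the 24-h control and 28-h misalignment
#' cycle lengths. Callers should restrict to flies that survived the week.
#'
#' @param series Ghost-filtered [beam_series()].
#' @param week Week index (1-based).
#' @param range_h Search range in hours.
#' @param alpha Significance level.
#' @return A `ccm_periodogram`.
#' @export
weekly_ld_rhythm <- function(series, week, range_h = c(16, 36), alpha = 0.01) {
  w <- week_window(week)
  if (w[2] > length(series$counts)) abort("week extends beyond the recorded span")
  chi2_periodogram(series$counts[(w[1] + 1):w[2]],
                   period_range_min = range_h * 60, alpha = alpha)
}

#' Free-running (DD) rhythmicity of one fly
#'
#' Periodogram over a constant-darkness epoch, excluding the first 24 h of
#' DD (activity is perturbed by the LD-to-DD transfer). Requires at least
#' `min_days` of DD after the exclusion.
#'
#' @param series Ghost-filtered [beam_series()].
#' @param schedule [light_schedule()] containing a DD epoch.
#' @param range_h Search range in hours (default 18-31 h, bracketing the
#'   ~24-h free-running period).
#' @param min_days Minimum analysable DD days after excluding day 1.
#' @param alpha Significance level.
#' @return A `ccm_periodogram` with attribute `window_minutes` (0-based,
#'   half-open offsets of the analysed window).
#' @export
dd_rhythm <- function(series, schedule, range_h = c(18, 31), min_days = 6,
                      alpha = 0.01) {
  i <- which(schedule$mode == "DD")[1]
  if (is.na(i)) abort("schedule has no DD epoch: free-running analysis undefined")
  start_min <- round(as.numeric(difftime(schedule$start[i], series$origin,
                                         units = "mins")))
  end_min <- min(round(as.numeric(difftime(schedule$end[i], series$origin,
                                           units = "mins"))),
                 length(series$counts))
  a <- start_min + MINUTES_PER_DAY              # skip first DD day
  if ((end_min - a) < min_days * MINUTES_PER_DAY) {
    abort(sprintf("insufficient DD span: %.1f d after excluding day 1 (need %d)",
                  (end_min - a) / MINUTES_PER_DAY, min_days))
  }
  pg <- chi2_periodogram(series$counts[(a + 1):end_min],
                         period_range_min = range_h * 60, alpha = alpha)
  attr(pg, "window_minutes") <- c(a, end_min)
  pg
}

#' Weekly rhythm table for a cohort
#'
#' Dominant period and power for every fly that survived each requested
#' week, under that fly's own schedule.
#'
#' @param cohort A `ccm_cohort`.
#' @param weeks Week indices.
#' @param range_h Periodogram search range in hours.
#' @return Tibble `fly_id`, `sex`, `treatment`, `week`,
#'   `dominant_period_min`, `power`, `rhythmic`.
#' @export
cohort_weekly_rhythm <- function(cohort, weeks = 1:3, range_h = c(16, 36)) {
  life <- cohort_lifespans(cohort)
  rows <- cohort[!cohort$excluded, ]
  purrr::map_dfr(weeks, function(wk) {
    keep <- which(survived_week(life$lifespan_minutes, wk))
    purrr::map_dfr(keep, function(k) {
      s <- filter_ghosts(rows$series[[k]])$series
      pg <- weekly_ld_rhythm(s, wk, range_h = range_h)
      tibble(fly_id = rows$fly_id[k], sex = rows$sex[k],
             treatment = rows$treatment[k], week = wk,
             dominant_period_min = dominant_period(pg),
             power = rhythm_power(pg), rhythmic = attr(pg, "rhythmic"))
    })
  })
}
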