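#' Plot a chi-squared periodogram
#'
#' Q statistic against trial period with the chi-squared significance line;
#' the dominant period is marked.
#'
#' @param object A `ccm_periodogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ccm_periodogram <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$period / 60)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$q)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sig), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = attr(object, "dominant_period") / 60,
                        colour = "red", linetype = "dotted") +
    ggplot2::labs(x = "Period (h)", y = expression(chi^2 ~ "periodogram Q"),
                  subtitle = sprintf("dominant period %.1f h, power %.1f",
                                     attr(object, "dominant_period") / 60,
                                     attr(object, "power"))) +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier survival curves
#'
#' Step curves of percent surviving with dotted 95% confidence bands, one
#' curve per group.
#'
#' @param data Lifespan table (e.g. from [cohort_lifespans()]).
#' @param time,group Columns (tidy-eval).
#' @return A ggplot.
#' @export
plot_survival <- function(data, time = lifespan_days, group = treatment) {
  groups <- dplyr::pull(data, {{ group }})
  curves <- purrr::map_dfr(unique(groups), function(g) {
    fit <- km_fit(data[groups == g, ], time = {{ time }})
    dplyr::mutate(tidy(fit), group = g)
  })
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, colour = .data$group)) +
    ggplot2::geom_step(ggplot2::aes(y = 100 * .data$estimate)) +
    ggplot2::geom_step(ggplot2::aes(y = 100 * .data$conf.low), linetype = "dotted") +
    ggplot2::geom_step(ggplot2::aes(y = 100 * .data$conf.high), linetype = "dotted") +
    ggplot2::labs(x = "Days", y = "Percent surviving", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a ZT-binned activity or sleep profile
#'
#' @param profile Output of [activity_profile()] or [sleep_profile()].
#' @param ylab Axis label (counts/min or min sleep per bin).
#' @return A ggplot with mean +/- SEM per zeitgeber-time bin.
#' @export
plot_profile <- function(profile, ylab = "Mean beam breaks/min") {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$zt_bin, y = .data$mean,
                                        fill = .data$treatment)) +
    ggplot2::geom_col(position = "dodge", width = 0.45) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           position = "dodge", width = 0.2) +
    ggplot2::labs(x = "Zeitgeber time (h)", y = ylab, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a mean normalized actogram
#'
#' Single-plotted: each row is 24 h of the averaged, per-fly-normalized
#' activity from [normalized_actogram()].
#'
#' @param acto Output of [normalized_actogram()].
#' @return A ggplot.
#' @export
plot_actogram <- function(acto) {
  ggplot2::ggplot(acto, ggplot2::aes(x = .data$minute_of_line / 60,
                                     y = .data$mean_norm_activity)) +
    ggplot2::geom_col(width = 1 / 60) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$line)) +
    ggplot2::labs(x = "Hours (each line = 24 h)", y = "Mean normalized activity") +
    ggplot2::theme_minimal()
}
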