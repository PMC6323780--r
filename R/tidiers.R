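#' Tidy a Kaplan-Meier fit
#'
#' @param x A `km_fit`.
#' @param ... Unused.
#' @return Tibble `time`, `n.risk`, `n.event`, `estimate`, `conf.low`,
#'   `conf.high` (log-log 95% CI).
#' @export
tidy.km_fit <- function(x, ...) {
  f <- x$fit
  tibble(time = f$time, n.risk = f$n.risk, n.event = f$n.event,
         estimate = f$surv, conf.low = f$lower, conf.high = f$upper)
}

#' One-row summary of a Kaplan-Meier fit
#'
#' @param x A `km_fit`.
#' @param ... Unused.
#' @return Tibble `n`, `events`, `median` (smallest time with survival
#'   <= 0.5; NA if never reached), `median.conf.low`, `median.conf.high`.
#' @export
glance.km_fit <- function(x, ...) {
  tab <- summary(x$fit)$table
  tibble(n = unname(tab["records"]), events = unname(tab["events"]),
         median = unname(tab["median"]),
         median.conf.low = unname(tab["0.95LCL"]),
         median.conf.high = unname(tab["0.95UCL"]))
}

#' Tidy a proportional-hazards model
#'
#' @param x A `hazard_model` from [cox_fit()].
#' @param ... Unused.
#' @return Tibble `term`, `estimate` (hazard ratio), `conf.low`,
#'   `conf.high` (Wald 95%), `p.value`.
#' @export
tidy.hazard_model <- function(x, ...) {
  s <- summary(x$fit)
  ci <- s$conf.int
  tibble(term = rownames(s$coefficients),
         estimate = unname(s$coefficients[, "exp(coef)"]),
         conf.low = unname(ci[, "lower .95"]),
         conf.high = unname(ci[, "upper .95"]),
         p.value = unname(s$coefficients[, "Pr(>|z|)"]))
}

#' One-row summary of a proportional-hazards model
#'
#' `ph_global_p` is the global Schoenfeld-residual test p-value; a small
#' value flags a proportional-hazards violation (reported, not modelled).
#'
#' @param x A `hazard_model`.
#' @param ... Unused.
#' @return Tibble `type`, `n`, `events`, `concordance`, `ph_global_p`.
#' @export
glance.hazard_model <- function(x, ...) {
  s <- summary(x$fit)
  php <- if (!is.null(x$ph_test)) unname(x$ph_test$table["GLOBAL", "p"]) else NA_real_
  tibble(type = x$type, n = s$n, events = unname(s$nevent),
         concordance = unname(s$concordance["C"]),
         ph_global_p = php)
}

#' Tidy a chi-squared periodogram
#'
#' @param x A `ccm_periodogram`.
#' @param ... Unused.
#' @return Tibble `period` (min), `q`, `sig`, `power` (q - sig).
#' @export
tidy.ccm_periodogram <- function(x, ...) {
  tibble(period = x$period, q = x$q, sig = x$sig, power = x$q - x$sig)
}

#' One-row summary of a chi-squared periodogram
#'
#' @param x A `ccm_periodogram`.
#' @param ... Unused.
#' @return Tibble `dominant_period_min`, `dominant_period_h`, `power`,
#'   `rhythmic`, `alpha`, `n_bins`.
#' @export
glance.ccm_periodogram <- function(x, ...) {
  tibble(dominant_period_min = attr(x, "dominant_period"),
         dominant_period_h = attr(x, "dominant_period") / 60,
         power = attr(x, "power"), rhythmic = attr(x, "rhythmic"),
         alpha = attr(x, "alpha"), n_bins = attr(x, "n"))
}
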