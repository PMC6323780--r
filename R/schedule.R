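#' Light schedules and zeitgeber time
#'
#' A light schedule is an ordered, contiguous set of epochs, each either
#' light-dark cycling (`"LD"`) with cycle length `period_h` (the T-cycle) and
#' `photoperiod_h` hours of light per cycle, or constant darkness (`"DD"`).
#' Each LD epoch starts at a lights-on event, which anchors zeitgeber time
#' (ZT0 = lights-on). Intervals are half-open: lights are on for
#' ZT in \[0, photoperiod) and off for ZT in \[photoperiod, T).
#'
#' The two schedules used in chronic-misalignment experiments are a 24-h
#' LD 12:12 control and a 28-h LD 14:14 misalignment schedule (daily 4-h
#' phase delays). Both deliver 84 h of light per 168-h week.
#'
#' @param epochs A data frame with columns `start`, `end` (POSIXct), `mode`
#'   (`"LD"` or `"DD"`), `period_h`, `photoperiod_h` (NA for DD epochs).
#'   Epochs must be in order and contiguous (`end[i] == start[i + 1]`).
#' @return A `light_schedule`: a tibble of epochs with class attributes.
#' @examples
#' t0 <- as.POSIXct("2024-01-01 08:00:00", tz = "UTC")
#' sched <- light_schedule(ld_epoch(t0, days = 28, period_h = 28, photoperiod_h = 14))
#' zt_of(sched, t0 + 3600 * 15) # 15 h after lights-on -> ZT 15
#' @export
light_schedule <- function(epochs) {
  epochs <- as_tibble(epochs)
  required <- c("start", "end", "mode", "period_h", "photoperiod_h")
  if (!all(required %in% names(epochs))) {
    abort(paste0("epochs must have columns: ", paste(required, collapse = ", ")))
  }
  if (nrow(epochs) == 0) abort("schedule needs at least one epoch")
  if (!all(epochs$mode %in% c("LD", "DD"))) abort("epoch mode must be 'LD' or 'DD'")
  ld <- epochs$mode == "LD"
  if (any(ld & (is.na(epochs$photoperiod_h) | epochs$photoperiod_h <= 0 |
                  epochs$photoperiod_h >= epochs$period_h))) {
    abort("LD epochs require 0 < photoperiod_h < period_h")
  }
  if (nrow(epochs) > 1) {
    gaps <- as.numeric(difftime(epochs$start[-1], epochs$end[-nrow(epochs)], units = "secs"))
    if (any(abs(gaps) > 1e-6)) abort("epochs must be contiguous and ordered")
  }
  if (any(epochs$end <= epochs$start)) abort("epoch end must be after start")
  structure(epochs, class = c("light_schedule", class(epochs)))
}

#' @rdname light_schedule
#' @param start Absolute time of the first lights-on (LD) or of DD onset.
#' @param days Epoch length in (24-h) days.
#' @param period_h T-cycle length in hours.
#' @param photoperiod_h Lights-on hours per cycle.
#' @export
ld_epoch <- function(start, days, period_h = 24, photoperiod_h = period_h / 2) {
  tibble(
    start = start, end = start + days * 86400,
    mode = "LD", period_h = period_h, photoperiod_h = photoperiod_h
  )
}

#' @rdname light_schedule
#' @export
dd_epoch <- function(start, days) {
  tibble(start = start, end = start + days * 86400, mode = "DD",
         period_h = NA_real_, photoperiod_h = NA_real_)
}

schedule_epoch_at <- function(schedule, timestamp) {
  i <- which(schedule$start <= timestamp & timestamp < schedule$end)
  if (length(i) != 1) abort("timestamp outside schedule span")
  i
}

#' Zeitgeber time of an absolute timestamp
#'
#' Hours since the most recent lights-on, modulo the epoch's cycle length T.
#' Defined only inside LD epochs; DD has no zeitgeber (use time-in-DD).
#'
#' @param schedule A [light_schedule()].
#' @param timestamp POSIXct time(s) inside an LD epoch.
#' @return Numeric ZT hours in \[0, T).
#' @export
zt_of <- function(schedule, timestamp) {
  vapply(as.list(timestamp), function(t) {
    i <- schedule_epoch_at(schedule, t)
    if (schedule$mode[i] != "LD") abort("ZT is undefined in DD epochs")
    h <- as.numeric(difftime(t, schedule$start[i], units = "hours"))
    h %% schedule$period_h[i]
  }, numeric(1))
}

#' Light state at an absolute timestamp
#'
#' @inheritParams zt_of
#' @param timestamp POSIXct time(s) within the schedule span.
#' @return Character vector, `"on"` or `"off"`. DD epochs are always off;
#'   in LD epochs lights are on iff ZT < photoperiod (half-open bound).
#' @export
lights_state <- function(schedule, timestamp) {
  vapply(as.list(timestamp), function(t) {
    i <- schedule_epoch_at(schedule, t)
    if (schedule$mode[i] == "DD") return("off")
    zt <- as.numeric(difftime(t, schedule$start[i], units = "hours")) %% schedule$period_h[i]
    if (zt < schedule$photoperiod_h[i]) "on" else "off"
  }, character(1))
}

#' Complete LD cycles within an analysis window
#'
#' A 168-h week contains 7 full cycles under T = 24 h but only 6 under
#' T = 28 h, which is what equalises weekly light and dark exposure between
#' the control and misalignment groups.
#'
#' @inheritParams zt_of
#' @param window_hours Window length in hours, anchored at a cycle start
#'   within a single LD epoch.
#' @param epoch Index of the LD epoch supplying T (default: first LD epoch).
#' @return Integer number of complete cycles, `floor(window_hours / T)`.
#' @export
full_cycles_in <- function(schedule, window_hours, epoch = which(schedule$mode == "LD")[1]) {
  if (is.na(epoch)) abort("schedule has no LD epoch")
  as.integer(floor(window_hours / schedule$period_h[epoch]))
}

#' @export
print.light_schedule <- function(x, ...) {
  cat("<light_schedule> ", nrow(x), " epoch(s)\n", sep = "")
  NextMethod()
}
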