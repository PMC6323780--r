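#' Simulation parameters for synthetic DAM cohorts
#'
#' The generator emulates the statistical structure the analysis pipeline
#' assumes: a two-state (active/rest) Markov chain whose rest probability is
#' shaped by the light schedule (consolidated night rest, a midday siesta,
#' and anticipation ramps beginning `anticipation_lag_h` hours after the
#' previous lighting transition), Poisson beam-break counts while active,
#' an age-dependent decline of the rhythmic component, Gompertz mortality
#' with a proportional-hazards treatment effect, and rare isolated "ghost"
#' counts after death.
#'
#' @param baseline_rate Expected beam breaks per active minute.
#' @param night_rest,day_rest,siesta_rest,anticipation_rest Stationary rest
#'   probabilities for night, baseline day, midday siesta and anticipation
#'   windows.
#' @param anticipation_lag_h Hours after the previous lighting transition at
#'   which anticipatory activity ramps begin (default 8.5 h).
#' @param startle_min,startle_factor Length (minutes) and rate multiplier of
#'   the sharply gated activity burst at each (subjective) lighting
#'   transition — the masking/startle response that gives entrained records
#'   their minute-sharp periodic features.
#' @param amplitude_decay Per-week multiplicative shrinkage of the rest-
#'   probability modulation towards its cycle mean (rhythm amplitude decline
#'   with age).
#' @param gompertz_a,gompertz_b Gompertz baseline hazard
#'   `h(t) = a * exp(b * t)` (t in days). The default `a` puts the control
#'   median lifespan at 23 days given `b`.
#' @param treatment_log_hr Log hazard ratio multiplying the hazard of
#'   misaligned (CCM) flies.
#' @param ghost_prob Per-fly probability of one isolated post-mortem count.
#' @param internal_period_min Free-running (DD) period of the internal
#'   clock, minutes.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(baseline_rate = 2,
                       night_rest = 0.88,
                       day_rest = 0.45,
                       siesta_rest = 0.75,
                       anticipation_rest = 0.12,
                       anticipation_lag_h = 8.5,
                       startle_min = 10,
                       startle_factor = 6,
                       amplitude_decay = 0.85,
                       gompertz_b = 0.15,
                       gompertz_a = gompertz_b * log(2) / expm1(gompertz_b * 23),
                       treatment_log_hr = log(1.94),
                       ghost_prob = 0.1,
                       internal_period_min = 1440) {
  stopifnot(baseline_rate >= 0, gompertz_a > 0, gompertz_b > 0,
            ghost_prob >= 0, ghost_prob <= 1, internal_period_min > 0)
  probs <- c(night_rest, day_rest, siesta_rest, anticipation_rest)
  if (any(probs < 0 | probs >= 1)) abort("rest probabilities must be in [0, 1)")
  structure(
    list(baseline_rate = baseline_rate, night_rest = night_rest,
         day_rest = day_rest, siesta_rest = siesta_rest,
         anticipation_rest = anticipation_rest,
         anticipation_lag_h = anticipation_lag_h,
         startle_min = startle_min, startle_factor = startle_factor,
         amplitude_decay = amplitude_decay,
         gompertz_a = gompertz_a, gompertz_b = gompertz_b,
         treatment_log_hr = treatment_log_hr, ghost_prob = ghost_prob,
         internal_period_min = internal_period_min),
    class = "sim_params"
  )
}

#' Closed-form Gompertz median lifespan
#'
#' For hazard `h(t) = a * exp(log_hr) * exp(b t)` the survival function is
#' `S(t) = exp(-(a e^{log_hr}/b) (e^{bt} - 1))`, giving the median in days.
#'
#' @param a,b Gompertz parameters (per day).
#' @param log_hr Log hazard-ratio multiplier (0 for baseline).
#' @return Median lifespan in days.
#' @export
gompertz_median_days <- function(a, b, log_hr = 0) {
  log1p(b * log(2) / (a * exp(log_hr))) / b
}

# inverse-CDF draw of a Gompertz death time (days) given uniform u
gompertz_draw_days <- function(u, a, b, log_hr = 0) {
  log1p(-b * log(u) / (a * exp(log_hr))) / b
}

# deterministic per-fly seed from (master seed, fly index); stays < 2^31
derive_seed <- function(master, index) {
  as.integer((((as.numeric(master) %% 97651) + 1) * 2654435761 +
                as.numeric(index) * 40503) %% 2147483647)
}

# Circadian coordinates for every minute of the horizon: subjective time
# ct_h (hours into the current cycle), cycle length t_h and photoperiod
# pp_h. In LD epochs these follow the schedule; in DD the clock free-runs
# at internal_period_min, continuing the phase held at lights-out of the
# preceding LD epoch.
minute_circadian <- function(schedule, origin, horizon_min, internal_period_min) {
  ct <- t_h <- pp <- numeric(horizon_min)
  mins <- seq_len(horizon_min) - 1
  stamps <- as.numeric(origin) + mins * 60
  for (i in seq_len(nrow(schedule))) {
    lo <- as.numeric(schedule$start[i]); hi <- as.numeric(schedule$end[i])
    sel <- stamps >= lo & stamps < hi
    if (!any(sel)) next
    if (schedule$mode[i] == "LD") {
      t_h[sel] <- schedule$period_h[i]
      pp[sel] <- schedule$photoperiod_h[i]
      ct[sel] <- ((stamps[sel] - lo) / 3600) %% schedule$period_h[i]
    } else {
      t_int <- internal_period_min / 60
      if (i > 1 && schedule$mode[i - 1] == "LD") {
        t_prev <- schedule$period_h[i - 1]
        pp_prev <- schedule$photoperiod_h[i - 1]
        phase0 <- ((lo - as.numeric(schedule$start[i - 1])) / 3600) %% t_prev
        phase0 <- phase0 * t_int / t_prev       # rescale into subjective hours
        pp_sub <- pp_prev * t_int / t_prev
      } else {
        phase0 <- 0
        pp_sub <- t_int / 2
      }
      t_h[sel] <- t_int
      pp[sel] <- pp_sub
      ct[sel] <- (phase0 + (stamps[sel] - lo) / 3600) %% t_int
    }
  }
  if (any(t_h == 0)) abort("schedule does not cover the simulation horizon")
  list(ct = ct, t_h = t_h, pp = pp)
}

# per-minute stationary rest probability before aging decay
rest_probability_base <- function(ct, t_h, pp, params) {
  p <- params
  r <- rep(p$day_rest, length(ct))
  day <- ct < pp
  siesta <- day & ct >= 0.35 * pp & ct < 0.65 * pp
  r[siesta] <- p$siesta_rest
  r[day & ct >= p$anticipation_lag_h] <- p$anticipation_rest   # evening anticipation
  r[day & ct < 1] <- p$anticipation_rest                       # lights-on response
  night <- !day
  r[night] <- p$night_rest
  r[night & ct < pp + 1] <- p$day_rest                         # activity offset tail
  morning <- night & ct >= pp + p$anticipation_lag_h           # morning anticipation
  r[morning] <- (p$night_rest + p$anticipation_rest) / 2
  r
}

# Minute-wise Markov switching probabilities over the horizon. Mean rest-
# bout length grows with rest propensity (5-30 min) so that scoreable
# (>= 5 min) sleep bouts occur at night but rarely in anticipation windows.
sim_switching_probs <- function(params, schedule, origin, horizon_min) {
  cc <- minute_circadian(schedule, origin, horizon_min, params$internal_period_min)
  r0 <- rest_probability_base(cc$ct, cc$t_h, cc$pp, params)
  week <- (seq_len(horizon_min) - 1) %/% MINUTES_PER_WEEK
  r_mean <- mean(r0)
  r <- r_mean + (r0 - r_mean) * params$amplitude_decay^week
  r <- pmin(pmax(r, 0.01), 0.98)
  startle <- (cc$ct %% cc$t_h) < params$startle_min / 60 |
    (cc$ct >= cc$pp & cc$ct < cc$pp + params$startle_min / 60)
  r[startle] <- 0.02
  mean_bout <- 5 + 25 * r
  p_exit <- 1 / mean_bout
  p_enter <- pmin(0.95, p_exit * r / (1 - r))
  boost <- ifelse(startle, params$startle_factor - 1, 0)
  rate_mult <- 1 + boost * params$amplitude_decay^week
  list(p_enter = p_enter, p_exit = p_exit, rate_mult = rate_mult)
}

#' Simulate one fly's beam-break record
#'
#' Minute counts arise from a two-state Markov chain with schedule-shaped
#' switching probabilities; active minutes emit Poisson(`baseline_rate`)
#' counts. The death time is drawn from a Gompertz distribution whose hazard
#' is multiplied by `exp(treatment_log_hr)` for `"CCM"` flies; all counts
#' after death are zero except an optional injected ghost (see
#' [inject_ghosts()]). When `baseline_rate > 0` a final beam break is placed
#' at the death minute, so the last activity marks death exactly. The result
#' is bit-reproducible given `seed`.
#'
#' @param params [sim_params()].
#' @param schedule [light_schedule()] spanning the horizon.
#' @param fly_id Identifier.
#' @param treatment `"control"` or `"CCM"`.
#' @param seed Integer seed for this fly.
#' @param sex `"female"` or `"male"` (metadata only).
#' @param probs Optional precomputed switching probabilities (internal;
#'   shared across a cohort for speed).
#' @return A `sim_fly`: list with `series` ([beam_series()]),
#'   `true_death_minute` (minutes since origin of the death beam break),
#'   `ghost_minute` (NA if none) and `meta` (one-row tibble).
#' @export
simulate_fly <- function(params, schedule, fly_id, treatment = "control",
                         seed = 1L, sex = "female", probs = NULL) {
  origin <- schedule$start[1]
  horizon_min <- floor(as.numeric(difftime(
    schedule$end[nrow(schedule)], origin, units = "mins")))
  if (horizon_min < MINUTES_PER_DAY) abort("simulation horizon must be at least 1 day")
  if (is.null(probs)) {
    probs <- sim_switching_probs(params, schedule, origin, horizon_min)
  }
  m <- if (identical(treatment, "CCM")) params$treatment_log_hr else 0
  set.seed(seed)
  death_days <- gompertz_draw_days(runif(1), params$gompertz_a, params$gompertz_b, m)
  true_death_minute <- min(floor(death_days * MINUTES_PER_DAY), horizon_min - 1L)
  u <- runif(horizon_min)
  states <- two_state_path(u, probs$p_enter, probs$p_exit)
  counts <- integer(horizon_min)
  active <- which(states == 1L)
  counts[active] <- rpois(length(active),
                          params$baseline_rate * probs$rate_mult[active])
  if (true_death_minute + 2 <= horizon_min) {
    counts[(true_death_minute + 2):horizon_min] <- 0L   # bin i covers minute i-1
  }
  if (params$baseline_rate > 0) {
    counts[true_death_minute + 1] <- max(counts[true_death_minute + 1], 1L)
  }
  fly <- structure(
    list(series = beam_series(fly_id, origin, counts),
         true_death_minute = true_death_minute,
         ghost_minute = NA_integer_,
         meta = tibble(fly_id = fly_id, sex = sex, treatment = treatment,
                       excluded = FALSE)),
    class = "sim_fly"
  )
  if (params$ghost_prob > 0) fly <- inject_ghosts(fly, params)
  fly
}

#' Inject a post-mortem ghost reading
#'
#' With probability `ghost_prob`, one beam-break count of 1 is placed at a
#' uniformly drawn minute more than 12 h after the fly's death, isolated
#' from all other activity (everything after death is zero). If the record
#' ends less than 12 h after death no ghost can be placed and a warning is
#' raised. Uses the current RNG stream; call after seeding for
#' reproducibility.
#'
#' @param fly A `sim_fly` from [simulate_fly()].
#' @param params [sim_params()] supplying `ghost_prob`.
#' @return The fly, possibly with a ghost count and `ghost_minute` set.
#' @export
inject_ghosts <- function(fly, params) {
  if (params$ghost_prob <= 0) return(fly)
  if (runif(1) >= params$ghost_prob) return(fly)
  horizon <- length(fly$series$counts)
  first_ok <- fly$true_death_minute + 721L        # gap strictly > 720 min
  if (first_ok > horizon - 1L) {
    warn("record ends < 12 h after death; ghost not placed")
    return(fly)
  }
  g <- first_ok + floor(runif(1) * (horizon - first_ok))  # minute offset
  fly$series$counts[g + 1L] <- 1L
  fly$ghost_minute <- as.integer(g)
  fly
}

#' Simulate a two-arm cohort
#'
#' Flies are generated independently with per-fly seeds derived by hashing
#' the master seed with the fly index, so each fly's record is reproducible
#' regardless of simulation order. Sexes alternate within each arm.
#'
#' @param n_per_group Flies per arm.
#' @param params [sim_params()].
#' @param schedule_control,schedule_ccm [light_schedule()]s for the two arms
#'   (must share origin and horizon).
#' @param seed Master seed.
#' @return A `ccm_cohort` tibble: `fly_id`, `sex`, `treatment`, `monitor`,
#'   `channel`, `excluded`, `true_death_minute`, `ghost_minute` and a
#'   `series` list-column; schedules attached as the `schedules` attribute.
#' @export
simulate_cohort <- function(n_per_group, params, schedule_control,
                            schedule_ccm, seed = 1L) {
  if (n_per_group < 1) abort("n_per_group must be >= 1")
  roster <- tibble(
    index = seq_len(2 * n_per_group),
    treatment = rep(c("control", "CCM"), each = n_per_group),
    sex = rep(rep_len(c("female", "male"), n_per_group), 2)
  )
  roster$fly_id <- sprintf("%s_%03d", ifelse(roster$treatment == "CCM", "ccm", "ctrl"),
                         rep(seq_len(n_per_group), 2))
  roster$monitor <- sprintf("M%02d", (roster$index - 1L) %/% 32L + 1L)
  roster$channel <- as.integer((roster$index - 1L) %% 32L + 1L)
  origin <- schedule_control$start[1]
  horizon <- floor(as.numeric(difftime(
    schedule_control$end[nrow(schedule_control)], origin, units = "mins")))
  probs <- list(
    control = sim_switching_probs(params, schedule_control, origin, horizon),
    CCM = sim_switching_probs(params, schedule_ccm,
                              schedule_ccm$start[1],
                              floor(as.numeric(difftime(
                                schedule_ccm$end[nrow(schedule_ccm)],
                                schedule_ccm$start[1], units = "mins"))))
  )
  n_unplaceable <- 0L
  flies <- purrr::pmap(roster, function(index, treatment, sex, fly_id, ...) {
    sched <- if (treatment == "CCM") schedule_ccm else schedule_control
    withCallingHandlers(
      simulate_fly(params, sched, fly_id, treatment,
                   seed = derive_seed(seed, index), sex = sex,
                   probs = probs[[treatment]]),
      warning = function(w) {
        if (grepl("ghost not placed", conditionMessage(w))) {
          n_unplaceable <<- n_unplaceable + 1L
          invokeRestart("muffleWarning")
        }
      })
  })
  if (n_unplaceable > 0) {
    rlang::inform(sprintf(
      "simulate_cohort: %d fly/flies died < 12 h before the end of recording; no ghost placed",
      n_unplaceable))
  }
  out <- roster[, c("fly_id", "sex", "treatment", "monitor", "channel")]
  out$excluded <- FALSE
  out$true_death_minute <- vapply(flies, `[[`, numeric(1), "true_death_minute")
  out$ghost_minute <- vapply(flies, function(f) as.numeric(f$ghost_minute), numeric(1))
  out$series <- purrr::map(flies, "series")
  attr(out, "schedules") <- list(control = schedule_control, CCM = schedule_ccm)
  class(out) <- c("ccm_cohort", class(out))
  out
}

#' Schedules attached to a simulated cohort
#' @param cohort A `ccm_cohort`.
#' @return Named list of [light_schedule()]s (`control`, `CCM`).
#' @export
cohort_schedules <- function(cohort) attr(cohort, "schedules")

#' Ground-truth table of a simulated cohort
#' @param cohort A `ccm_cohort`.
#' @return Tibble `fly_id`, `true_death_minute`, `group`.
#' @export
cohort_truth <- function(cohort) {
  tibble(fly_id = cohort$fly_id,
         true_death_minute = cohort$true_death_minute,
         group = cohort$treatment)
}

#' Write a simulated cohort as DAM monitor files plus metadata
#'
#' One monitor file per 32 flies (`M01.txt`, ...), a `metadata.tsv` with the
#' fly table, and a `truth.tsv` with programmed death minutes for recovery
#' tests.
#'
#' @param cohort A `ccm_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  schedules <- cohort_schedules(cohort)
  for (mon in unique(cohort$monitor)) {
    rows <- cohort[cohort$monitor == mon, ]
    horizon <- length(rows$series[[1]]$counts)
    origin <- rows$series[[1]]$origin
    sched <- schedules[[if (rows$treatment[1] == "CCM") "CCM" else "control"]]
    stamps <- origin + (seq_len(horizon) - 1L) * 60
    counts <- matrix(0L, nrow = horizon, ncol = 32,
                     dimnames = list(NULL, sprintf("ch%02d", 1:32)))
    for (k in seq_len(nrow(rows))) {
      counts[, rows$channel[k]] <- rows$series[[k]]$counts
    }
    readings <- dplyr::bind_cols(
      tibble(reading = seq_len(horizon), timestamp = stamps,
             status = 1L, valid = TRUE,
             light = as.integer(lights_state(sched, stamps) == "on")),
      as_tibble(counts)
    )
    write_dam_file(readings, file.path(dir, paste0(mon, ".txt")))
  }
  readr::write_tsv(
    cohort[, c("fly_id", "sex", "treatment", "monitor", "channel", "excluded")],
    file.path(dir, "metadata.tsv"))
  readr::write_tsv(cohort_truth(cohort), file.path(dir, "truth.tsv"))
  invisible(dir)
}
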