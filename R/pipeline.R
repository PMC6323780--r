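#' Default pipeline configuration
#'
#' All thresholds default to the analysis' canonical values: 12-h ghost
#' isolation, 5-min sleep rule, 0.5 min/hr sleep-matching tolerance, 0.01
#' periodogram significance, 0.1/0.3 regulation-classification FDRs, a
#' 24-h LD 12:12 control schedule and a 28-h LD 14:14 misalignment
#' schedule.
#'
#' @param seed Master seed; every random draw in the run flows from it.
#' @param n_per_group Simulated flies per arm.
#' @param days Experiment span in (24-h) days.
#' @param sim Named list of [sim_params()] overrides.
#' @param weeks Weeks to summarise for sleep/activity/rhythm.
#' @param de_ccm,de_aging Optional paths to DE tables for
#'   [classify_regulation()].
#' @return A config list, serialisable with [yaml::write_yaml()].
#' @export
pipeline_config <- function(seed = 1L, n_per_group = 20L, days = 45L,
                            sim = list(), weeks = 1:3,
                            de_ccm = NULL, de_aging = NULL) {
  list(seed = seed, n_per_group = n_per_group, days = days, sim = sim,
       weeks = weeks,
       schedule = list(control = list(period_h = 24, photoperiod_h = 12),
                       ccm = list(period_h = 28, photoperiod_h = 14)),
       match_tolerance = 0.5,
       de_ccm = de_ccm, de_aging = de_aging)
}

build_schedules <- function(config, origin = as.POSIXct("2024-01-01 08:00:00",
                                                        tz = "UTC")) {
  list(
    control = light_schedule(ld_epoch(origin, days = config$days,
                                      period_h = config$schedule$control$period_h,
                                      photoperiod_h = config$schedule$control$photoperiod_h)),
    CCM = light_schedule(ld_epoch(origin, days = config$days,
                                  period_h = config$schedule$ccm$period_h,
                                  photoperiod_h = config$schedule$ccm$photoperiod_h))
  )
}

#' Run the full misalignment analysis pipeline
#'
#' Simulates (or accepts) a two-arm cohort, then runs ghost filtering,
#' death calling, Kaplan-Meier/log-rank/Cox survival analysis, weekly sleep
#' and activity summaries, sleep-matched Cox analysis, weekly rhythm
#' estimation and (optionally) DE cross-classification. Deterministic given
#' the config seed; re-running with the same config reproduces the report
#' byte for byte.
#'
#' @param config A [pipeline_config()] list, or a path to a YAML file with
#'   the same fields.
#' @param out_dir Optional directory; when given, writes `lifespans.tsv`,
#'   `survival.tsv`, `weekly_summaries.tsv`, `rhythm.tsv`,
#'   `classified_genes.tsv` (if DE inputs given) and `report.json`.
#' @param cohort Optional pre-built `ccm_cohort` (e.g. read from monitor
#'   files); when NULL a cohort is simulated from the config.
#' @return The report as a nested list (invisibly a tibble-free structure
#'   serialisable to JSON).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         cohort = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file '%s' not found", config))
    config <- utils::modifyList(pipeline_config(), yaml::read_yaml(config))
  }
  for (p in c(config$de_ccm, config$de_aging)) {
    if (!is.null(p) && !file.exists(p)) abort(sprintf("input path '%s' not found", p))
  }
  if (is.null(cohort)) {
    params <- do.call(sim_params, config$sim)
    schedules <- build_schedules(config)
    cohort <- simulate_cohort(config$n_per_group, params,
                              schedules$control, schedules$CCM,
                              seed = config$seed)
  }

  life <- cohort_lifespans(cohort)
  life$ccm <- as.integer(life$treatment == "CCM")
  km <- purrr::map(split(life, life$treatment), km_fit)
  medians <- purrr::map_dbl(km, ~ glance(.x)$median)
  lr <- logrank_test(life)
  cox_uni <- cox_fit(life, "ccm")

  weekly <- cohort_weekly_summaries(cohort, weeks = config$weeks)
  wk1 <- weekly[weekly$week == 1 & weekly$included, ]
  sleep1 <- dplyr::transmute(wk1, fly_id = .data$fly_id, sleep = .data$sleep_min_per_hr)
  life_sleep <- dplyr::inner_join(
    life, dplyr::transmute(wk1, fly_id = .data$fly_id,
                           sleep_h_per_day = .data$sleep_min_per_hr * 24 / 60),
    by = "fly_id")
  cox_multi <- tryCatch(cox_fit(life_sleep, c("ccm", "sleep_h_per_day")),
                        error = function(e) NULL)
  matched <- sleep_match(
    sleep1[sleep1$fly_id %in% life$fly_id[life$treatment == "control"], ],
    sleep1[sleep1$fly_id %in% life$fly_id[life$treatment == "CCM"], ],
    tolerance = config$match_tolerance)
  cox_matched <- if (nrow(matched) >= 2) {
    sub <- life[life$fly_id %in% c(matched$control_id, matched$ccm_id), ]
    tryCatch(cox_fit(sub, "ccm"), error = function(e) NULL)
  }
  corr <- tryCatch(
    correlate_sleep_longevity(dplyr::inner_join(
      wk1, life[, c("fly_id", "lifespan_days")], by = "fly_id")),
    error = function(e) NULL)

  rhythm <- cohort_weekly_rhythm(cohort, weeks = config$weeks)

  de <- NULL
  if (!is.null(config$de_ccm) && !is.null(config$de_aging)) {
    classified <- classify_regulation(read_de_table(config$de_ccm),
                                      read_de_table(config$de_aging))
    de <- list(classified = classified,
               counts = regulation_counts(classified))
  }

  report <- list(
    seed = config$seed,
    n_flies = nrow(life),
    median_lifespan_days = as.list(medians),
    percent_median_reduction = percent_median_reduction(medians[["control"]],
                                                        medians[["CCM"]]),
    logrank = as.list(lr),
    cox = list(
      univariate = as.list(tidy(cox_uni)[1, ]),
      multivariate = if (!is.null(cox_multi)) purrr::transpose(tidy(cox_multi)),
      sleep_matched = if (!is.null(cox_matched)) as.list(tidy(cox_matched)[1, ]),
      n_matched_pairs = nrow(matched)
    ),
    sleep_longevity_correlation = if (!is.null(corr)) as.list(corr),
    rhythm_period_by_group = as.list(tapply(
      rhythm$dominant_period_min[rhythm$week == 1],
      rhythm$treatment[rhythm$week == 1], stats::median)),
    de_counts = if (!is.null(de)) {
      stats::setNames(as.list(de$counts$n),
                      paste(de$counts$regulation_class, de$counts$ccm_direction,
                            sep = "_"))
    }
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(life, file.path(out_dir, "lifespans.tsv"))
    surv_tab <- purrr::imap_dfr(km, ~ dplyr::mutate(tidy(.x), treatment = .y))
    readr::write_tsv(surv_tab, file.path(out_dir, "survival.tsv"))
    readr::write_tsv(weekly, file.path(out_dir, "weekly_summaries.tsv"))
    readr::write_tsv(rhythm, file.path(out_dir, "rhythm.tsv"))
    if (!is.null(de)) {
      readr::write_tsv(de$classified, file.path(out_dir, "classified_genes.tsv"))
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
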