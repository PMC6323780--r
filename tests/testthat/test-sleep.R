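flanked <- function(zeros) {
  beam_series("f", T0, c(1L, integer(zeros), 1L))
}

test_that("five consecutive inactive minutes score as sleep, fewer do not", {
  s10 <- score_sleep(flanked(10))
  expect_equal(sum(s10$asleep, na.rm = TRUE), 10)
  expect_equal(nrow(s10$bouts), 1)
  expect_equal(s10$bouts$length, 10)
  expect_equal(s10$bouts$start_minute, 1)

  s4 <- score_sleep(flanked(4))
  expect_equal(sum(s4$asleep, na.rm = TRUE), 0)
  expect_equal(nrow(s4$bouts), 0)
})

test_that("sleep scoring matches the minute-scan oracle on random series", {
  set.seed(5)
  for (i in 1:200) {
    counts <- rpois(1440, 0.35)
    s <- beam_series("r", T0, counts)
    got <- score_sleep(s)
    expect_identical(got$asleep, sleep_oracle(counts))
    expect_true(all(got$bouts$length >= 5))
    # idempotence: re-scoring the asleep-masked series changes nothing
    expect_identical(score_sleep(s)$asleep, got$asleep)
  }
})

test_that("scoring truncates at death: post-mortem minutes are neither state", {
  counts <- c(1L, integer(20), 1L, integer(30))
  s <- beam_series("d", T0, counts)
  sc <- score_sleep(s, lifespan_minutes = 21)
  expect_true(all(is.na(sc$asleep[23:length(counts)])))
  expect_equal(sum(sc$asleep, na.rm = TRUE), 20)
})

test_that("weekly summaries follow the week-survivor rule and units", {
  n <- 2 * 10080
  all_zero <- beam_series("az", T0, c(integer(n - 1), 1L))
  w <- weekly_sleep_summary(all_zero, 1, lifespan_minutes = n - 1)
  expect_true(w$included)
  expect_equal(w$sleep_min_per_hr, 60)            # degenerate: fully asleep

  dies_midweek <- weekly_sleep_summary(all_zero, 1, lifespan_minutes = 5000)
  expect_false(dies_midweek$included)
  expect_true(is.na(dies_midweek$sleep_min_per_hr))
  expect_false(weekly_activity_summary(all_zero, 1, 5000)$included)

  # half asleep: alternate 30 zero-minutes and 30 active minutes
  half <- beam_series("h", T0, rep(c(integer(30), rep(1L, 30)), n / 60))
  expect_equal(weekly_sleep_summary(half, 1, n - 1)$sleep_min_per_hr, 30)

  const <- beam_series("c", T0, rep(1L, n))
  expect_equal(weekly_activity_summary(const, 1, n - 1)$activity_per_min, 1)
  expect_error(weekly_sleep_summary(const, 3, n - 1), "beyond")
})

test_that("weekly sleep plus wake accounts for all 10,080 minutes", {
  p <- sim_params(ghost_prob = 0)
  f <- simulate_fly(p, sched_24(days = 8), "w", seed = 21)
  stopifnot(f$true_death_minute >= 10080)
  sc <- score_sleep(f$series, f$true_death_minute)
  wk <- sc$asleep[1:10080]
  expect_equal(sum(wk) + sum(!wk), 10080)
})

test_that("full-life metrics exclude the last three days", {
  n <- 6 * 1440
  uniform <- beam_series("u", T0, rep(1L, n))
  fl <- fulllife_summary(uniform, lifespan_minutes = n - 1)
  expect_true(fl$included)
  expect_equal(fl$activity_per_min, 1)
  expect_equal(fl$sleep_min_per_hr, 0)

  # active only in the last 3 days of life -> full-life activity 0
  late <- beam_series("l", T0, c(integer(3 * 1440), rep(1L, 3 * 1440)))
  fl2 <- fulllife_summary(late, lifespan_minutes = n - 1)
  expect_equal(fl2$activity_per_min, 0)
  expect_equal(fl2$sleep_min_per_hr, 60)

  short <- fulllife_summary(uniform, lifespan_minutes = 72 * 60)
  expect_false(short$included)
})

test_that("profiles fold onto the ZT grid with 2T bins and conserve means", {
  # single control fly, constant 2 counts/min, alive all 2 weeks
  n <- 2 * 10080
  const <- beam_series("c1", T0, rep(2L, n))
  co <- make_test_cohort(list(const), "control",
                         schedule_control = sched_24(days = 15))
  ap <- activity_profile(co, week = 1)
  expect_equal(nrow(ap), 48)                       # 2T bins for T = 24
  expect_true(all(ap$mean == 2))
  expect_true(all(ap$sem == 0))
  expect_equal(ap$n, rep(1L, 48))

  # CCM fly: 56 bins spanning ZT 0-28
  const28 <- beam_series("m1", T0, rep(1L, n))
  co28 <- make_test_cohort(list(const28), "CCM", schedule_ccm = sched_28(days = 15))
  ap28 <- activity_profile(co28, week = 1)
  expect_equal(nrow(ap28), 56)
  expect_equal(max(ap28$zt_bin), 27.5)

  # square-wave fly: on for ZT 0-12, off ZT 12-24; matches folding oracle
  day_pattern <- rep(c(rep(3L, 720), integer(720)), 14)
  sq <- beam_series("s1", T0, day_pattern)
  cosq <- make_test_cohort(list(sq), "control",
                           schedule_control = sched_24(days = 14))
  apsq <- activity_profile(cosq, week = 1)
  expect_true(all(apsq$mean[apsq$zt_bin < 12] == 3))
  expect_true(all(apsq$mean[apsq$zt_bin >= 12] == 0))
  # conservation: mean of bin means equals the overall weekly rate
  expect_equal(mean(apsq$mean), mean(day_pattern[1:10080]))
})

test_that("sleep profiles report minutes per bin between 0 and the bin width", {
  n <- 2 * 10080
  # 30 min asleep / 30 min active, phase-locked to ZT (1440 %% 60 == 0):
  # even ZT bins carry exactly 30 min of sleep, odd bins none
  alternating <- beam_series("a", T0, rep(c(integer(30), rep(1L, 30)), n / 60))
  co <- make_test_cohort(list(alternating), "control",
                         schedule_control = sched_24(days = 15))
  sp <- sleep_profile(co, week = 1)
  expect_equal(nrow(sp), 48)
  expect_equal(sp$mean, rep(c(30, 0), 24))

  never <- beam_series("b", T0, rep(1L, n))
  co2 <- make_test_cohort(list(never), "control",
                          schedule_control = sched_24(days = 15))
  sp2 <- sleep_profile(co2, week = 1)
  expect_true(all(sp2$mean == 0))
})

test_that("normalized actograms are scale-invariant with unit mean", {
  n <- 3 * 1440
  base <- rep(c(rep(2L, 720), integer(720)), 3)
  f1 <- beam_series("n1", T0, c(base, integer(n)))
  f2 <- beam_series("n2", T0, c(base * 3L, integer(n)))
  co <- make_test_cohort(list(f1, f2), "control",
                         schedule_control = sched_24(days = 6))
  acto <- normalized_actogram(co, window_minutes = c(0, n))
  expect_equal(max(acto$line), 3)
  expect_equal(mean(acto$mean_norm_activity), 1, tolerance = 1e-12)
  # doubling every fly's counts changes nothing
  f1b <- beam_series("n1", T0, c(base * 2L, integer(n)))
  f2b <- beam_series("n2", T0, c(base * 6L, integer(n)))
  cob <- make_test_cohort(list(f1b, f2b), "control",
                          schedule_control = sched_24(days = 6))
  expect_equal(normalized_actogram(cob, c(0, n))$mean_norm_activity,
               acto$mean_norm_activity)
  # constant-activity fly alone -> all 1.0
  cc <- make_test_cohort(list(beam_series("c", T0, rep(4L, n))), "control",
                         schedule_control = sched_24(days = 3))
  expect_true(all(normalized_actogram(cc, c(0, n))$mean_norm_activity == 1))
  # zero-activity fly excluded with a warning
  co0 <- make_test_cohort(list(f1, beam_series("z", T0, integer(n * 2))),
                          "control", schedule_control = sched_24(days = 6))
  expect_warning(normalized_actogram(co0, c(0, n)), "zero mean")
})

test_that("sleep-longevity correlation matches a rank-then-Pearson oracle", {
  d_up <- tibble::tibble(sleep_min_per_hr = 1:6, lifespan_days = c(2, 4, 6, 7, 9, 12))
  expect_equal(correlate_sleep_longevity(d_up)$rho, 1)
  d_dn <- tibble::tibble(sleep_min_per_hr = 1:6, lifespan_days = rev(c(2, 4, 6, 7, 9, 12)))
  expect_equal(correlate_sleep_longevity(d_dn)$rho, -1)

  set.seed(9)
  d <- tibble::tibble(sleep_min_per_hr = runif(10, 10, 40),
                      lifespan_days = runif(10, 10, 30))
  got <- correlate_sleep_longevity(d)
  oracle <- cor(rank(d$sleep_min_per_hr), rank(d$lifespan_days))
  expect_equal(got$rho, oracle, tolerance = 1e-12)
  expect_true(got$conf.low <= got$rho && got$rho <= got$conf.high)

  const <- tibble::tibble(sleep_min_per_hr = rep(5, 6), lifespan_days = 1:6)
  expect_error(correlate_sleep_longevity(const), "degenerate")
  expect_error(correlate_sleep_longevity(d_up[1:3, ]), "at least 4")
})
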