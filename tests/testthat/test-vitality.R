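series_with <- function(len, at, counts = 1L, id = "f") {
  x <- integer(len)
  x[at + 1L] <- counts            # `at` are 0-based minute offsets
  beam_series(id, T0, x)
}

test_that("ghost filtering removes only bilaterally isolated late counts", {
  life <- c(seq(0, 19920, by = 240), 20000)  # dense activity up to minute 20000

  # activity ends at minute 20000; single count 13.3 h later is a ghost
  s <- series_with(22000, c(life, 20800))
  fg <- filter_ghosts(s)
  expect_equal(fg$ghost_minutes, 20800)
  expect_equal(fg$series$counts[20801], 0L)

  # 11 h after previous activity: below threshold, retained
  s2 <- series_with(22000, c(life, 20000 + 660))
  expect_length(filter_ghosts(s2)$ghost_minutes, 0)

  # two counts 13 h late but 30 min apart: not isolated, both retained
  s3 <- series_with(22000, c(life, 20780, 20810))
  expect_length(filter_ghosts(s3)$ghost_minutes, 0)

  # chain: once the first late count is retained, the second anchors on it
  s4 <- series_with(44000, c(life, 20780, 20810, 21500))
  expect_length(filter_ghosts(s4)$ghost_minutes, 0)

  # two isolated late counts more than 12 h apart are both ghosts
  s5 <- series_with(44000, c(life, 20800, 41000))
  expect_equal(filter_ghosts(s5)$ghost_minutes, c(20800, 41000))
})

test_that("ghost filtering never increases lifespan; gapless series unchanged", {
  set.seed(42)
  for (i in 1:50) {
    at <- sort(sample(0:9999, 30))
    s <- series_with(10000, at)
    fg <- filter_ghosts(s)
    expect_lte(call_death(fg$series)$lifespan_minutes,
               call_death(s)$lifespan_minutes)
    if (max(diff(c(0, at))) <= 720) {
      expect_identical(fg$series$counts, s$counts)
    }
  }
})

test_that("death is called at the last beam break", {
  s <- series_with(3000, c(0, 700, 1440))
  d <- call_death(s)
  expect_equal(d$lifespan_minutes, 1440)
  expect_equal(d$lifespan_days, 1)
  s_end <- series_with(500, c(0, 499))
  expect_equal(call_death(s_end)$lifespan_minutes, 499)  # series length - 1
  expect_error(call_death(beam_series("f", T0, integer(10))), "no evidence")
})

test_that("simulator truth survives ghost injection and death calling", {
  p <- sim_params(ghost_prob = 1)
  co <- simulate_cohort(25, p, sched_24(days = 40), sched_28(days = 40), seed = 2)
  life <- cohort_lifespans(co)
  expect_equal(life$lifespan_minutes, co$true_death_minute)
  expect_equal(sum(life$n_ghosts), sum(!is.na(co$ghost_minute)))
})

test_that("KM estimator drops 1/n per event and reproduces closed forms", {
  d <- tibble::tibble(lifespan_days = c(3, 1, 4, 2, 5))
  fit <- km_fit(d)
  td <- tidy(fit)
  expect_equal(td$estimate, seq(0.8, 0, by = -0.2))
  expect_equal(glance(fit)$median, 3)            # smallest t with S <= 0.5

  single <- km_fit(tibble::tibble(lifespan_days = 7))
  expect_equal(tidy(single)$estimate, 0)
  expect_equal(tidy(single)$time, 7)

  set.seed(1)
  lam <- 0.1
  big <- tibble::tibble(lifespan_days = rexp(2000, lam))
  expect_lt(abs(glance(km_fit(big))$median - log(2) / lam) / (log(2) / lam), 0.03)
})

test_that("log-rank statistic matches the hand-computed O-E/V oracle", {
  d <- tibble::tibble(lifespan_days = c(1, 2, 3, 10, 20, 30),
                      treatment = rep(c("a", "b"), each = 3))
  lr <- logrank_test(d)
  # textbook oracle: sum over event times of observed minus expected in
  # group a, with hypergeometric variance
  times <- sort(unique(d$lifespan_days))
  o <- e <- v <- 0
  for (t in times) {
    at_risk <- d$lifespan_days >= t
    n <- sum(at_risk); na <- sum(at_risk & d$treatment == "a")
    dth <- sum(d$lifespan_days == t)
    o <- o + sum(d$lifespan_days == t & d$treatment == "a")
    e <- e + dth * na / n
    if (n > 1) v <- v + dth * (na / n) * (1 - na / n) * (n - dth) / (n - 1)
  }
  expect_equal(lr$statistic, (o - e)^2 / v, tolerance = 1e-9)
  expect_equal(lr$statistic, 5.0517, tolerance = 1e-4)   # frozen value

  swapped <- dplyr::mutate(d, treatment = ifelse(treatment == "a", "b", "a"))
  expect_equal(logrank_test(swapped)$statistic, lr$statistic)

  same <- tibble::tibble(lifespan_days = rep(c(1, 2, 3), 2),
                         treatment = rep(c("a", "b"), each = 3))
  lr0 <- logrank_test(same)
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p.value, 1)
  expect_error(logrank_test(d[d$treatment == "a", ]), "two non-empty")
})

test_that("Cox coefficient matches a brute-force partial-likelihood grid", {
  # interleaved groups keep the partial likelihood bounded (an all-early
  # treated group separates perfectly and the MLE diverges)
  d <- tibble::tibble(lifespan_days = c(1, 2, 3, 4), group = c(1, 0, 1, 0))
  hm <- cox_fit(d, "group")
  # no ties: log partial likelihood is exact
  logpl <- function(beta) {
    x <- d$group[order(d$lifespan_days)]
    sum(vapply(seq_along(x), function(i) {
      beta * x[i] - log(sum(exp(beta * x[i:length(x)])))
    }, numeric(1)))
  }
  grid <- seq(-5, 5, by = 1e-4)
  beta_hat <- grid[which.max(vapply(grid, logpl, numeric(1)))]
  expect_equal(unname(coef(hm$fit)), beta_hat, tolerance = 1e-3)

  flipped <- dplyr::mutate(d, group = 1 - group)
  expect_equal(tidy(cox_fit(flipped, "group"))$estimate,
               1 / tidy(hm)$estimate, tolerance = 1e-8)

  expect_error(cox_fit(dplyr::mutate(d, group = 1), "group"), "constant")
  expect_error(cox_fit(d, "nope"), "not in data")
})

test_that("Cox recovery and null calibration hold on exponential cohorts", {
  set.seed(33)
  n <- 1000
  d <- tibble::tibble(
    group = rep(c(0, 1), each = n),
    lifespan_days = c(rexp(n, 1), rexp(n, 2))   # true HR = 2
  )
  hr <- tidy(cox_fit(d, "group"))$estimate
  expect_gt(hr, 1.8); expect_lt(hr, 2.2)
})

test_that("sleep matching pairs within tolerance and attains maximum size", {
  p1 <- sleep_match(tibble::tibble(fly_id = "c1", sleep = 10.0),
                    tibble::tibble(fly_id = "m1", sleep = 10.4))
  expect_equal(nrow(p1), 1)
  expect_equal(p1$ccm_id, "m1")
  p2 <- sleep_match(tibble::tibble(fly_id = "c1", sleep = 10.0),
                    tibble::tibble(fly_id = "m1", sleep = 10.6))
  expect_equal(nrow(p2), 0)

  # nearest-neighbour greedy would drop a pair here; ours must not
  ctl <- tibble::tibble(fly_id = c("c1", "c2"), sleep = c(0, 0.4))
  ccm <- tibble::tibble(fly_id = c("m1", "m2"), sleep = c(-0.5, 0.4))
  expect_equal(nrow(sleep_match(ctl, ccm)), 2)

  set.seed(7)
  for (i in 1:10) {
    a <- round(runif(5, 0, 4), 2)
    b <- round(runif(5, 0, 4), 2)
    got <- nrow(sleep_match(tibble::tibble(fly_id = paste0("c", 1:5), sleep = a),
                            tibble::tibble(fly_id = paste0("m", 1:5), sleep = b)))
    expect_equal(got, max_matching_oracle(a, b, 0.5))
  }
  # no fly appears twice; all pairs within tolerance
  a <- c(1, 1.2, 1.3); b <- c(1.1, 1.1, 5)
  m <- sleep_match(tibble::tibble(fly_id = paste0("c", 1:3), sleep = a),
                   tibble::tibble(fly_id = paste0("m", 1:3), sleep = b))
  expect_false(any(duplicated(m$ccm_id)))
  expect_true(all(abs(m$sleep_diff) <= 0.5))
})

test_that("printed-statistic arithmetic is reproduced exactly", {
  expect_equal(percent_median_reduction(23.7, 20.2), 14.8)
  expect_equal(percent_median_reduction(23.0, 19.6), 14.8)
  expect_equal(percent_median_reduction(5, 5), 0)
  expect_error(percent_median_reduction(0, 1), "positive")

  expect_identical(hazard_percent(1.94), 94L)
  expect_identical(hazard_percent(1), 0L)
  expect_identical(hazard_percent(0.74), -26L)
  expect_error(hazard_percent(-1), "positive")

  expect_equal(equivalent_sleep_loss(1.49, 0.77), 1.5)
  expect_equal(equivalent_sleep_loss(1, 0.77), 0)
  expect_equal(equivalent_sleep_loss(2, 0.5), 1)
  expect_error(equivalent_sleep_loss(1.5, 1.01), "protective")
})
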