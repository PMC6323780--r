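# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's own implementations (direct loops, split/apply) so
# they stay valid cross-checks.

T0 <- as.POSIXct("2024-01-01 08:00:00", tz = "UTC")

sched_24 <- function(days = 16) {
  light_schedule(ld_epoch(T0, days = days, period_h = 24, photoperiod_h = 12))
}
sched_28 <- function(days = 16) {
  light_schedule(ld_epoch(T0, days = days, period_h = 28, photoperiod_h = 14))
}

# chi-squared periodogram by naive fold-and-average:
# Q(P) = K * sum_h (M_h - M)^2 / s2, K = N/P, s2 = overall variance (MLE)
fold_oracle_q <- function(x, p) {
  n <- length(x)
  groups <- ((seq_len(n) - 1) %% p) + 1
  m_h <- vapply(seq_len(p), function(h) mean(x[groups == h]), numeric(1))
  m <- mean(x)
  s2 <- sum((x - m)^2) / n
  (n / p) * sum((m_h - m)^2) / s2
}

# run-length sleep scorer: explicit minute-by-minute scan
sleep_oracle <- function(counts, min_bout = 5) {
  n <- length(counts)
  asleep <- rep(FALSE, n)
  i <- 1
  while (i <= n) {
    if (counts[i] == 0) {
      j <- i
      while (j < n && counts[j + 1] == 0) j <- j + 1
      if (j - i + 1 >= min_bout) asleep[i:j] <- TRUE
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  asleep
}

# maximum bipartite matching size via augmenting paths (exact)
max_matching_oracle <- function(ctrl, ccm, tol = 0.5) {
  feasible <- outer(ctrl, ccm, function(a, b) abs(a - b) <= tol)
  match_of_ccm <- rep(0L, length(ccm))
  visited <- rep(FALSE, length(ccm))
  try_augment <- function(i) {
    for (j in which(feasible[i, ])) {
      if (!visited[j]) {
        visited[j] <<- TRUE           # shared per-augmentation marker
        if (match_of_ccm[j] == 0L || try_augment(match_of_ccm[j])) {
          match_of_ccm[j] <<- i
          return(TRUE)
        }
      }
    }
    FALSE
  }
  size <- 0L
  for (i in seq_along(ctrl)) {
    visited <- rep(FALSE, length(ccm))
    if (try_augment(i)) size <- size + 1L
  }
  size
}

# rule-by-rule regulation classifier, coded independently of the package
classify_oracle <- function(ccm_fc, ccm_p, ag_fc, ag_p,
                            ccm_fdr = 0.1, strict = 0.1, trend = 0.3,
                            opp = 0.3) {
  if (is.na(ccm_fc) || is.na(ccm_p) || is.na(ag_fc) || is.na(ag_p)) {
    return("unclassified")
  }
  if (ccm_p >= ccm_fdr) return("not_ccm_significant")
  if (ccm_fc == 0 || ag_fc == 0) return("unclassified")
  same_dir <- (ccm_fc > 0) == (ag_fc > 0)
  if (same_dir) {
    if (ag_p < strict) return("convergent")
    if (ag_p < trend) return("trend_same")
    return("unclassified")
  }
  if (ag_p < opp) return("opposite")
  "unclassified"
}

# build a minimal cohort tibble around hand-crafted series
make_test_cohort <- function(series_list, treatment,
                             schedule_control = sched_24(),
                             schedule_ccm = sched_28()) {
  n <- length(series_list)
  out <- tibble::tibble(
    fly_id = vapply(series_list, function(s) s$fly_id, character(1)),
    sex = rep_len(c("female", "male"), n),
    treatment = treatment,
    monitor = "M01",
    channel = seq_len(n),
    excluded = FALSE,
    true_death_minute = NA_real_,
    ghost_minute = NA_real_,
    series = series_list
  )
  attr(out, "schedules") <- list(control = schedule_control, CCM = schedule_ccm)
  class(out) <- c("ccm_cohort", class(out))
  out
}
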