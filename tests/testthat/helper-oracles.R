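# Independent oracles and random-data generators shared across tests.

# Brute-force unweighted log-rank z: per-risk-set hypergeometric tabulation
# written as a plain loop with set counting, independent of the package's
# vectorised implementation.
oracle_logrank_z <- function(a, b) {
  time <- c(a$time, b$time)
  event <- c(a$event, b$event)
  grp <- rep(c(1L, 2L), c(nrow(a), nrow(b)))
  u <- 0
  v <- 0
  for (tt in sort(unique(time[event == 1L]))) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == 1L)
    d <- sum(time == tt & event == 1L)
    d1 <- sum(time == tt & event == 1L & grp == 1L)
    u <- u + (d1 - d * n1 / n)
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  u / sqrt(v)
}

# Brute-force survivor fraction for event-only data: direct counting.
oracle_survivor_fraction <- function(times, t) {
  vapply(t, function(x) mean(times > x), numeric(1))
}

# Random survival dataset: mixed events/censorings, occasional ties.
random_dataset <- function(n, rate = 0.1, censor_p = 0.3, tie_round = NA) {
  t <- stats::rexp(n, rate)
  if (!is.na(tie_round)) t <- round(t, tie_round)
  survival_data(t, stats::rbinom(n, 1, 1 - censor_p))
}
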