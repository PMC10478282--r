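test_that("identical groups give z = 0 and swapping groups flips the sign", {
  set.seed(1)
  d <- random_dataset(30)
  r <- weighted_logrank(d, d)
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)

  a <- random_dataset(25)
  b <- random_dataset(20, rate = 0.2)
  r_ab <- weighted_logrank(a, b, fh_weights(1, 1))
  r_ba <- weighted_logrank(b, a, fh_weights(1, 1))
  expect_equal(r_ab$z, -r_ba$z)
  expect_equal(r_ab$p, r_ba$p)
  expect_equal(r_ab$chi2, r_ab$z^2)
})

test_that("FH(0,0) agrees with the brute-force risk-set oracle and survdiff", {
  set.seed(23)
  for (i in 1:30) {
    a <- random_dataset(sample(3:25, 1), tie_round = sample(c(NA, 1), 1))
    b <- random_dataset(sample(3:25, 1), tie_round = sample(c(NA, 1), 1))
    if (sum(a$event) + sum(b$event) == 0) b$event[1] <- 1L
    r <- suppressWarnings(weighted_logrank(a, b))
    expect_equal(r$z, oracle_logrank_z(a, b), tolerance = 1e-10)
    if (abs(r$z) > 1e-8) {
      sd <- survival::survdiff(
        survival::Surv(time, event) ~ g,
        data = data.frame(
          time = c(a$time, b$time), event = c(a$event, b$event),
          g = rep(1:2, c(nrow(a), nrow(b)))
        )
      )
      expect_equal(r$chi2, sd$chisq, tolerance = 1e-8)
    }
  }
})

test_that("degenerate variance and empty-event inputs are handled", {
  one <- survival_data(1, 1)
  expect_warning(r <- weighted_logrank(one, survival_data(1, 1)), "zero variance")
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)
  cens <- survival_data(c(2, 3), c(0, 0))
  expect_error(weighted_logrank(cens, cens), "no events")
  expect_error(weighted_logrank(survival_data(numeric(0)), one), "empty dataset")
})

test_that("FH weights are monotone along event times", {
  set.seed(5)
  for (i in 1:10) {
    a <- random_dataset(30)
    b <- random_dataset(30, rate = 0.15)
    tab <- tteval:::logrank_table(a, b)
    w10 <- tab$s_left^1 # FH(1,0): pooled survival, non-increasing
    w01 <- (1 - tab$s_left)^1 # FH(0,1): non-decreasing
    expect_true(all(diff(w10) <= 1e-12))
    expect_true(all(diff(w01) >= -1e-12))
  }
})

test_that("maxcombo selects by |z| with first-in-order ties and Bonferroni", {
  set.seed(9)
  d <- random_dataset(25)
  mc0 <- maxcombo(d, d) # all four z = 0: tie broken to the first test
  expect_equal(mc0$selected, 1L)
  expect_equal(mc0$p_adjusted, 1)

  for (i in 1:15) {
    a <- random_dataset(30)
    b <- random_dataset(30, rate = 0.2)
    mc <- maxcombo(a, b)
    zs <- vapply(mc$per_test, `[[`, numeric(1), "z")
    expect_equal(mc$selected, which.max(abs(zs)))
    expect_equal(mc$p_adjusted, min(1, 4 * mc$p_raw))
    expect_gte(mc$p_adjusted, mc$p_raw)
  }
})

test_that("late separation mostly selects the late-weighted test", {
  set.seed(31)
  early <- event_dist("exponential", rate = 0.08)
  late <- event_dist("piecewise_exponential", rates = c(0.08, 0.015), breaks = 10)
  sel <- replicate(120, {
    a <- survival_data(tteval:::draw_event_times(early, 120))
    b <- survival_data(tteval:::draw_event_times(late, 120))
    maxcombo(a, b)$selected
  })
  expect_gt(mean(sel == 4L), 0.5) # FH(0,1) the majority pick
})

test_that("the PH diagnostic is calibrated under proportional hazards", {
  set.seed(13)
  met <- replicate(200, {
    a <- survival_data(stats::rexp(50, 0.1))
    b <- survival_data(stats::rexp(50, 0.1))
    check_ph(a, b)$met
  })
  expect_gt(mean(met), 0.90) # ~95% expected at alpha = 0.05
})

test_that("crossing hazards are flagged as PH violations", {
  set.seed(17)
  d1 <- event_dist("piecewise_exponential", rates = c(0.05, 0.30), breaks = 8)
  d2 <- event_dist("piecewise_exponential", rates = c(0.30, 0.05), breaks = 8)
  met <- replicate(40, {
    a <- survival_data(tteval:::draw_event_times(d1, 150))
    b <- survival_data(tteval:::draw_event_times(d2, 150))
    check_ph(a, b)$met
  })
  expect_lt(mean(met), 0.5)
})

test_that("degenerate PH fits are flagged not evaluable", {
  a <- survival_data(c(1, 2, 3), c(1, 0, 0)) # a single event
  b <- survival_data(c(4, 5, 6), c(1, 1, 1))
  r <- check_ph(a, b)
  expect_false(r$evaluable)
  expect_true(r$met)

  set.seed(2)
  d <- random_dataset(40, censor_p = 0.2)
  r2 <- check_ph(d, d) # identical groups: coefficient 0, not significant
  expect_true(r2$evaluable)
  expect_true(r2$met)
})
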