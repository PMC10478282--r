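test_that("within-tolerance PFS/OS pairs are removed as deaths", {
  out <- derive_ttp(
    survival_data(c(3, 5, 9)),
    survival_data(c(5.02, 12))
  )
  expect_equal(out$ttp$time, c(3, 9))
  expect_equal(out$report$n_death_removed, 1)
  expect_equal(out$report$matched_pairs$pfs_time, 5)
  expect_equal(out$report$matched_pairs$os_time, 5.02)

  # all OS times beyond tolerance: nothing matched
  out2 <- derive_ttp(survival_data(c(3, 5, 9)), survival_data(c(6, 12)))
  expect_equal(out2$ttp$time, c(3, 5, 9))
  expect_equal(out2$report$n_death_removed, 0)
})

test_that("censored PFS records are removed and counted", {
  out <- derive_ttp(
    survival_data(c(2, 4, 7), c(0, 1, 0)),
    survival_data(numeric(0))
  )
  expect_equal(out$ttp$time, 4)
  expect_equal(out$report$n_censored_removed, 2)
  expect_equal(out$report$n_ttp, 1)
  expect_error(derive_ttp(survival_data(numeric(0)), survival_data(1)), "empty")
})

test_that("report counts always sum to the PFS input size", {
  set.seed(20)
  for (i in 1:30) {
    n <- sample(1:60, 1)
    pfs <- survival_data(stats::rexp(n, 0.1), stats::rbinom(n, 1, 0.7))
    m <- sample(0:40, 1)
    os <- survival_data(stats::rexp(m + 1, 0.05)[seq_len(m)], rep(1, m))
    rep_out <- derive_ttp(pfs, os)$report
    expect_equal(
      rep_out$n_censored_removed + rep_out$n_death_removed + rep_out$n_ttp,
      rep_out$n_input_pfs
    )
  }
})

test_that("record order never changes the derived TTP multiset", {
  set.seed(21)
  pfs <- survival_data(stats::rexp(30, 0.1), stats::rbinom(30, 1, 0.8))
  os <- survival_data(pmax(0, pfs$time[1:10] + stats::runif(10, -0.05, 0.05)))
  ref <- sort(derive_ttp(pfs, os)$ttp$time)
  for (i in 1:5) {
    p <- sample(nrow(pfs))
    q <- sample(nrow(os))
    out <- derive_ttp(
      survival_data(pfs$time[p], pfs$event[p]),
      survival_data(os$time[q], os$event[q])
    )
    expect_equal(sort(out$ttp$time), ref)
  }
})

test_that("matching is one-to-one, prefers the nearest OS event, and flags ambiguity", {
  # two PFS events compete for one OS event; each OS event used at most once
  out <- derive_ttp(
    survival_data(c(5.00, 5.03)),
    survival_data(c(5.01))
  )
  expect_equal(out$report$n_death_removed, 1)
  expect_equal(out$report$matched_pairs$pfs_time, 5.00) # nearest (processed first)
  expect_equal(out$ttp$time, 5.03)

  # one PFS event with two eligible OS candidates: ambiguity is counted
  out2 <- derive_ttp(
    survival_data(5.0),
    survival_data(c(4.98, 5.01))
  )
  expect_equal(out2$report$n_ambiguous, 1)
  expect_equal(out2$report$matched_pairs$os_time, 5.01) # closest candidate
})

test_that("a separated competing-risks cohort recovers exactly the deaths", {
  # progression and death times kept > 0.2 months apart (beyond the 2-day
  # tolerance), so the derivation must recover the death set exactly;
  # deaths *after* progression stay in the OS list but match nothing
  prog <- seq(0.5, 20, by = 0.5) # 40 progression events
  deaths_first <- seq(0.7, 18.7, by = 2) # 10 deaths before progression
  cens <- c(2.2, 6.2, 11.2) # censored follow-up
  pfs <- survival_data(
    c(prog, deaths_first, cens),
    c(rep(1, length(prog) + length(deaths_first)), rep(0, length(cens)))
  )
  os <- survival_data(c(deaths_first, prog[1:5] + 0.3)) # + late deaths
  out <- derive_ttp(pfs, os)
  expect_equal(out$report$n_death_removed, length(deaths_first))
  expect_equal(out$report$n_censored_removed, length(cens))
  expect_equal(sort(out$ttp$time), prog)
  expect_equal(sort(out$report$matched_pairs$os_time), deaths_first)
})
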