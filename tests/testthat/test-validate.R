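test_that("a correct model validates on all six methods under exact observation", {
  set.seed(40)
  pool <- simulate_model_pool(2e4, event_dist("exponential", rate = 0.08))
  scen <- trial_scenario(
    "exact-null", event_dist("exponential", rate = 0.08),
    event_dist("exponential", rate = 0.08),
    visit_interval = 0, seed = 77L
  )
  tr <- simulate_trial(scen)
  v <- tte_validate(pool, tr$reported, n_iter = 200, seed = 11)
  expect_s3_class(v, "tte_validation")
  expect_equal(nrow(v$metrics), 6)
  expect_true(all(v$metrics$validated))
  expect_true(all(v$metrics$value >= 80))
  # PH-violation ratios only attach to the test-based methods
  expect_true(all(is.na(v$metrics$ph_violation[1:2])))
  expect_true(all(!is.na(v$metrics$ph_violation[3:6])))
})

test_that("a grossly wrong model fails the test-based methods", {
  set.seed(41)
  pool <- survival_data(stats::rexp(5000, 0.08) + 50)
  obs <- survival_data(stats::rexp(60, 0.08))
  v <- tte_validate(pool, obs,
    n_iter = 60, seed = 12, check_ph = FALSE,
    methods = c("raw_coverage", "boot_logrank", "boot_maxcombo")
  )
  vals <- stats::setNames(v$metrics$value, v$metrics$method)
  expect_lt(vals["boot_logrank"], 5)
  expect_lt(vals["boot_maxcombo"], 5)
  expect_false(any(v$metrics$validated))
})

test_that("identical seeds reproduce the whole report", {
  set.seed(42)
  pool <- survival_data(stats::rexp(3000, 0.08))
  obs <- survival_data(stats::rexp(50, 0.08))
  v1 <- tte_validate(pool, obs, n_iter = 50, seed = 9, check_ph = FALSE)
  v2 <- tte_validate(pool, obs, n_iter = 50, seed = 9, check_ph = FALSE)
  expect_identical(v1$metrics, v2$metrics)
  expect_identical(v1$pi$lo, v2$pi$lo)
})

test_that("juncture never falls below raw coverage in a validation run", {
  set.seed(43)
  for (i in 1:5) {
    pool <- survival_data(stats::rexp(2000, stats::runif(1, 0.05, 0.15)))
    obs <- survival_data(stats::rexp(40, 0.08))
    v <- tte_validate(pool, obs,
      n_iter = 40, seed = i,
      methods = c("raw_coverage", "juncture"), check_ph = FALSE
    )
    vals <- stats::setNames(v$metrics$value, v$metrics$method)
    expect_gte(vals["juncture"], vals["raw_coverage"])
  }
})

test_that("comparison tables are signed and antisymmetric", {
  set.seed(44)
  pool <- survival_data(stats::rexp(2000, 0.08))
  obs1 <- survival_data(stats::rexp(40, 0.08))
  obs2 <- survival_data(stats::rexp(40, 0.12))
  v1 <- tte_validate(pool, obs1, n_iter = 30, seed = 1, check_ph = FALSE)
  v2 <- tte_validate(pool, obs2, n_iter = 30, seed = 1, check_ph = FALSE)
  self <- compare_validations(v1, v1, labels = c("a", "b"))
  expect_true(all(self$diff_a_minus_b == 0))
  ab <- compare_validations(v1, v2, labels = c("a", "b"))
  ba <- compare_validations(v2, v1, labels = c("b", "a"))
  expect_equal(ab$diff_a_minus_b, -ba$diff_b_minus_a)
  v3 <- tte_validate(pool, obs1,
    n_iter = 30, seed = 1, check_ph = FALSE,
    methods = "raw_coverage"
  )
  expect_error(compare_validations(v1, v3), "mismatched method lists")
})

test_that("the JSON report carries metrics, config and fingerprints", {
  set.seed(45)
  pool <- survival_data(stats::rexp(1000, 0.08))
  obs <- survival_data(stats::rexp(30, 0.08))
  v <- tte_validate(pool, obs, n_iter = 20, seed = 2, check_ph = FALSE)
  path <- withr::local_tempfile(fileext = ".json")
  write_validation_json(v, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$schema, "tteval/validation-report/v1")
  expect_length(parsed$methods, 6)
  expect_equal(parsed$inputs$observed$n, 30)
  got <- vapply(parsed$methods, function(m) m$metric_value_pct, numeric(1))
  expect_equal(got, v$metrics$value)
})
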