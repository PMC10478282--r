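test_that("the time grid is the midpoints of equal cells", {
  g <- time_grid(10, 4)
  expect_equal(as.numeric(g), c(1.25, 3.75, 6.25, 8.75))
  expect_equal(attr(g, "t_end"), 10)
  expect_error(time_grid(-1), "positive")
  expect_error(time_grid(10, 0), ">= 1")
})

test_that("degenerate pools give zero-width prediction intervals", {
  pool <- survival_data(rep(4, 50))
  g <- time_grid(8, 20)
  pi95 <- build_prediction_interval(pool, 10, 25, g)
  expect_equal(pi95$lo, pi95$hi)
  expect_equal(pi95$lo, as.numeric(g < 4)) # step down at the common time

  set.seed(4)
  pool2 <- survival_data(stats::rexp(100, 0.1))
  one <- build_prediction_interval(pool2, 30, 1, g)
  expect_equal(one$lo, one$hi) # a single iteration brackets nothing
})

test_that("interval bounds bracket the analytic survivor function", {
  set.seed(99)
  pool <- survival_data(stats::rexp(5e4, 0.1))
  g <- time_grid(10, 100)
  pi95 <- build_prediction_interval(pool, 74, 1500, g)
  i10 <- length(g) # grid point closest to t = 10
  expect_lt(pi95$lo[i10], exp(-1))
  expect_gt(pi95$hi[i10], exp(-1))
  # pointwise quantile bounds of non-increasing curves are non-increasing
  expect_true(all(diff(pi95$lo) <= 1e-12))
  expect_true(all(diff(pi95$hi) <= 1e-12))
  expect_error(build_prediction_interval(pool, 1e6, 10, g), "pool smaller")
})

test_that("raw coverage counts closed-interval inclusion on the grid", {
  g <- time_grid(10, 100)
  # observed flat at 1 versus an interval pinned at 0: nothing covered
  obs_far <- fit_km(survival_data(rep(50, 20)))
  pool_tiny <- survival_data(rep(0.001, 100))
  pi0 <- build_prediction_interval(pool_tiny, 20, 10, g)
  expect_equal(raw_coverage(obs_far, pi0), 0)

  # a band that everywhere contains the observed curve: full coverage
  set.seed(5)
  obs <- fit_km(survival_data(stats::rexp(40, 0.1)))
  s <- as.numeric(evaluate_km(obs, g))
  pi1 <- prediction_interval(g, pmax(0, s - 0.05), pmin(1, s + 0.05))
  expect_equal(raw_coverage(obs, pi1), 100)
  # touching a bound counts as covered
  pi2 <- prediction_interval(g, s, s)
  expect_equal(raw_coverage(obs, pi2), 100)
})

test_that("juncture detects any overlap and validates its grid", {
  g <- time_grid(10, 50)
  lo <- rep(0.4, 50)
  hi <- rep(0.6, 50)
  pi95 <- prediction_interval(g, lo, hi)
  expect_equal(juncture(observation_band(g, lo, hi), pi95), 100)
  expect_equal(juncture(observation_band(g, rep(0.7, 50), rep(0.9, 50)), pi95), 0)
  band_touch <- observation_band(g, rep(0.6, 50), rep(0.9, 50))
  expect_equal(juncture(band_touch, pi95), 100) # shared endpoint counts
  expect_error(juncture(observation_band(g[-1], lo[-1], hi[-1]), pi95),
    "mismatched grids"
  )
})

test_that("interval constructors reject invalid bounds", {
  g <- time_grid(5, 10)
  expect_error(prediction_interval(g, rep(0.5, 10), rep(0.4, 10)), "lo <= hi")
  expect_error(prediction_interval(g, seq(0, 0.9, length.out = 10), rep(1, 10)),
    "non-increasing"
  )
  expect_error(observation_band(g, rep(-0.1, 10), rep(0.5, 10)), "lo <= hi")
})

test_that("inflating the prediction interval never lowers the metrics", {
  set.seed(14)
  for (i in 1:10) {
    d <- random_dataset(40, rate = 0.08)
    obs <- fit_km(d)
    g <- time_grid(max(d$time), 60)
    pool <- survival_data(stats::rexp(2000, stats::runif(1, 0.04, 0.2)))
    pi95 <- build_prediction_interval(pool, 40, 60, g)
    wide <- prediction_interval(
      g, pmax(0, pi95$lo - 0.1), pmin(1, pi95$hi + 0.1)
    )
    band <- otu_band(d, observation_scheme(2), g)
    expect_gte(raw_coverage(obs, wide), raw_coverage(obs, pi95))
    expect_gte(juncture(band, wide), juncture(band, pi95))
  }
})
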