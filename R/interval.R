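#' Uniform evaluation grid over the observation window
#'
#' The window `[0, t_end]` is split into `n` equal cells and the grid is the
#' set of cell midpoints. With a midpoint grid, the fraction of grid points
#' falling in a union of sub-intervals whose endpoints are cell boundaries
#' equals the length ratio of that union exactly, so point-counting metrics
#' (raw coverage, juncture) agree with their length-based definitions.
#'
#' @param t_end right end of the observation window (months, > 0). Choose
#'   `t_end` no larger than the observed maximum follow-up so no
#'   extrapolated observed values enter the metrics.
#' @param n number of grid points (default 1000).
#' @return Numeric vector of class `"time_grid"` with attributes `t_end`
#'   and `n`.
#' @export
time_grid <- function(t_end, n = 1000L) {
  t_end <- as.numeric(t_end)
  n <- as.integer(n)
  if (is.na(t_end) || t_end <= 0) stop("t_end must be positive")
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  h <- t_end / n
  structure(seq(h / 2, t_end - h / 2, length.out = n),
    t_end = t_end, n = n, class = "time_grid"
  )
}

#' Prediction interval from explicit bounds
#'
#' Container for the pointwise 95% prediction band of the simulated survival
#' curve. Usually produced by [build_prediction_interval()]; the constructor
#' is exposed for analytically specified bands. Bounds must be valid
#' probabilities, pointwise ordered, and each non-increasing in time
#' (pointwise quantiles of non-increasing step curves).
#'
#' @param grid time grid, strictly increasing.
#' @param lo,hi per-point lower (2.5%) and upper (97.5%) bounds.
#' @param n_iter,sample_size provenance metadata (optional).
#' @return An object of class `"prediction_interval"`.
#' @export
prediction_interval <- function(grid, lo, hi, n_iter = NA_integer_,
                                sample_size = NA_integer_) {
  grid <- as.numeric(grid)
  if (!length(grid)) stop("empty grid")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  if (length(lo) != length(grid) || length(hi) != length(grid)) {
    stop("lo/hi must match the grid length")
  }
  eps <- 1e-10
  if (any(lo < -eps) || any(hi > 1 + eps) || any(lo > hi + eps)) {
    stop("bounds must satisfy 0 <= lo <= hi <= 1")
  }
  if (any(diff(lo) > eps) || any(diff(hi) > eps)) {
    stop("lo and hi must each be non-increasing in t")
  }
  structure(
    list(
      grid = grid, lo = pmin(pmax(lo, 0), 1), hi = pmin(pmax(hi, 0), 1),
      n_iter = n_iter, sample_size = sample_size
    ),
    class = "prediction_interval"
  )
}

# Event-free probabilities of one bootstrap subsample on the grid.
# All-event samples reduce to the empirical survivor function, which avoids
# a survfit call in the hot bootstrap loop; mixed samples take the KM path.
sample_surv_on_grid <- function(time, event, grid) {
  if (all(event == 1L)) {
    st <- sort(time)
    1 - findInterval(grid, st) / length(st)
  } else {
    d <- survival_data(time, event)
    as.numeric(evaluate_km(fit_km(d), pmin(grid, max(time))))
  }
}

#' Bootstrapped 95% prediction interval of the simulated curve
#'
#' Repeats `n_iter` times: draw a subsample of `sample_size` predicted
#' times-to-event from the simulated pool (the size of the real cohort, so
#' statistical power matches the clinical study), fit a Kaplan-Meier curve,
#' and evaluate it on the grid. The pointwise empirical 2.5% and 97.5%
#' quantiles across iterations form the prediction interval.
#'
#' @param pool simulated pool of predicted times-to-event (all events).
#' @param sample_size per-iteration subsample size; must not exceed the pool
#'   size when sampling without replacement.
#' @param n_iter number of bootstrap iterations (>= 1).
#' @param grid a [time_grid()] (or numeric, strictly increasing).
#' @param replace sample with replacement? Default `FALSE`: a sample is
#'   *taken from* the pool; negligible difference when the pool is much
#'   larger than the sample.
#' @return A `"prediction_interval"` object.
#' @examples
#' pool <- survival_data(stats::rexp(2000, 0.1))
#' pi95 <- build_prediction_interval(pool, 74, 200, time_grid(10, 100))
#' @export
build_prediction_interval <- function(pool, sample_size, n_iter, grid,
                                      replace = FALSE) {
  pool <- as_survival_data(pool)
  sample_size <- as.integer(sample_size)
  n_iter <- as.integer(n_iter)
  if (n_iter < 1L) stop("n_iter must be >= 1")
  if (!replace && nrow(pool) < sample_size) {
    stop("pool smaller than sample_size")
  }
  grid <- as.numeric(grid)
  if (!length(grid)) stop("empty grid")

  m <- matrix(NA_real_, nrow = n_iter, ncol = length(grid))
  for (i in seq_len(n_iter)) {
    idx <- sample.int(nrow(pool), sample_size, replace = replace)
    m[i, ] <- sample_surv_on_grid(pool$time[idx], pool$event[idx], grid)
  }
  lo <- apply(m, 2, stats::quantile, probs = 0.025, names = FALSE)
  hi <- apply(m, 2, stats::quantile, probs = 0.975, names = FALSE)
  prediction_interval(grid, lo, hi,
    n_iter = n_iter, sample_size = sample_size
  )
}

#' @export
print.prediction_interval <- function(x, ...) {
  cat(sprintf(
    "95%% prediction interval: %d grid points on [%.3g, %.3g]\n",
    length(x$grid), min(x$grid), max(x$grid)
  ))
  if (!is.na(x$n_iter)) {
    cat(sprintf(
      "  %d bootstrap iterations, subsample size %d\n",
      x$n_iter, x$sample_size
    ))
  }
  cat(sprintf("  mean width %.4g\n", mean(x$hi - x$lo)))
  invisible(x)
}

#' Write a prediction interval to CSV
#'
#' Columns `t`, `lo`, `hi`, for external plotting.
#'
#' @param pi a `"prediction_interval"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interval_csv <- function(pi, path) {
  stopifnot(inherits(pi, "prediction_interval"))
  utils::write.csv(data.frame(t = pi$grid, lo = pi$lo, hi = pi$hi),
    path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Raw coverage of the observed curve by the prediction interval
#'
#' Percentage of the observation window where the observed Kaplan-Meier
#' curve lies inside the bootstrapped prediction interval of the simulated
#' curve (closed intervals: touching a bound counts as covered). Computed as
#' the fraction of grid points satisfying `lo(t) <= S_obs(t) <= hi(t)`; on
#' the uniform midpoint grid this equals the covered-length ratio.
#'
#' @param observed a `"km_curve"` fitted to the observed cohort, evaluable
#'   on the interval's grid.
#' @param pi a `"prediction_interval"`.
#' @return Percentage in `[0, 100]`.
#' @export
raw_coverage <- function(observed, pi) {
  stopifnot(inherits(observed, "km_curve"), inherits(pi, "prediction_interval"))
  if (!length(pi$grid)) stop("empty grid")
  s <- evaluate_km(observed, pi$grid)
  if (any(attr(s, "extrapolated"))) {
    warning("grid extends beyond observed follow-up; extrapolated values used")
  }
  s <- as.numeric(s)
  100 * mean(pi$lo <= s & s <= pi$hi)
}

#' Juncture of the observation band and the prediction interval
#'
#' Percentage of the observation window where the observation variability
#' band and the prediction interval share at least one value, i.e.
#' `band.lo <= pi.hi` and `pi.lo <= band.hi` (even a partial overlap
#' counts). Unlike raw coverage this accounts for the observation time
#' uncertainty instead of assuming the event occurred exactly when reported.
#'
#' @param band an `"observation_band"`.
#' @param pi a `"prediction_interval"` on the same grid.
#' @return Percentage in `[0, 100]`.
#' @export
juncture <- function(band, pi) {
  stopifnot(inherits(band, "observation_band"), inherits(pi, "prediction_interval"))
  if (length(band$grid) != length(pi$grid) ||
    !isTRUE(all.equal(as.numeric(band$grid), as.numeric(pi$grid)))) {
    stop("mismatched grids")
  }
  100 * mean(band$lo <= pi$hi & pi$lo <= band$hi)
}
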