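#' Observation scheme: the inter-visit delay
#'
#' In clinical routine an event is only detected at the next scheduled
#' visit, so the reported time-to-event (RTTE) overestimates the true time
#' by at most one inter-visit delay. That delay is the observation time
#' uncertainty (OTU), expressed in months.
#'
#' @param otu_width positive inter-visit delay, months.
#' @return An object of class `"observation_scheme"`.
#' @export
observation_scheme <- function(otu_width) {
  otu_width <- as.numeric(otu_width)
  if (length(otu_width) != 1L || is.na(otu_width) || otu_width <= 0) {
    stop("otu_width must be a positive number of months")
  }
  structure(list(otu_width = otu_width), class = "observation_scheme")
}

#' Shift all events one full OTU earlier
#'
#' Deterministic shift used to build the observation variability band: every
#' *event* time t becomes `max(0, t - otu_width)`. Censored records are left
#' unchanged — censoring is an administrative time, not an observed event.
#' Times clipped at zero are counted in the `"n_clipped"` attribute.
#'
#' @param data a survival dataset.
#' @param scheme an [observation_scheme()].
#' @return A shifted `"survival_data"` object.
#' @export
shift_events_full <- function(data, scheme) {
  data <- as_survival_data(data)
  stopifnot(inherits(scheme, "observation_scheme"))
  t <- data$time
  ev <- data$event == 1L
  shifted <- ifelse(ev, t - scheme$otu_width, t)
  n_clip <- sum(shifted < 0)
  out <- survival_data(pmax(0, shifted), data$event, label = attr(data, "label"))
  attr(out, "n_clipped") <- n_clip
  out
}

#' Random per-patient OTU shift
#'
#' For the test-based validation variants the unknown true event time is
#' modelled by assigning each patient an independent draw
#' `u ~ Uniform(-otu_width, 0)` and moving the record to `max(0, t + u)`.
#' All records (events and censored) are shifted — the draw is assigned to
#' the patient, not to the event. Event flags are unchanged. A fresh draw is
#' taken at every call, so bootstrap iterations get independent shifts.
#'
#' @inheritParams shift_events_full
#' @return A shifted `"survival_data"` object.
#' @export
sample_otu_shift <- function(data, scheme) {
  data <- as_survival_data(data)
  stopifnot(inherits(scheme, "observation_scheme"))
  u <- stats::runif(nrow(data), min = -scheme$otu_width, max = 0)
  survival_data(pmax(0, data$time + u), data$event,
    label = attr(data, "label")
  )
}

#' Observation variability band from explicit bounds
#'
#' Container for the band between the reported survival curve and its fully
#' OTU-shifted counterpart, evaluated on a time grid. Usually produced by
#' [otu_band()]; the constructor is exposed for analytically specified bands
#' (worked examples, plotting).
#'
#' @param grid time grid (see [time_grid()]), strictly increasing.
#' @param lo,hi per-point lower/upper event-free probabilities,
#'   `0 <= lo <= hi <= 1`.
#' @return An object of class `"observation_band"`.
#' @export
observation_band <- function(grid, lo, hi) {
  grid <- as.numeric(grid)
  if (!length(grid)) stop("empty grid")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  if (length(lo) != length(grid) || length(hi) != length(grid)) {
    stop("lo/hi must match the grid length")
  }
  if (any(lo < -1e-12) || any(hi > 1 + 1e-12) || any(lo > hi + 1e-12)) {
    stop("band bounds must satisfy 0 <= lo <= hi <= 1")
  }
  structure(
    list(grid = grid, lo = pmin(pmax(lo, 0), 1), hi = pmin(pmax(hi, 0), 1)),
    class = "observation_band"
  )
}

#' Observation variability band of a reported dataset
#'
#' Bounds, at each grid point, the reported Kaplan-Meier curve and the curve
#' refitted after shifting all events one full OTU earlier
#' ([shift_events_full()]). Since events moved earlier can only lower
#' survival, the shifted curve is the lower edge and the reported curve the
#' upper edge; any event factually occurring inside this band would have
#' been reported on the observed curve.
#'
#' @param data the reported survival dataset (or a `"km_curve"` fitted to
#'   it, which carries its data).
#' @param scheme an [observation_scheme()].
#' @param grid evaluation grid within `[0, max follow-up]` of the reported
#'   data.
#' @return An `"observation_band"` object.
#' @export
otu_band <- function(data, scheme, grid) {
  if (inherits(data, "km_curve")) data <- data$data
  data <- as_survival_data(data)
  stopifnot(inherits(scheme, "observation_scheme"))
  grid <- as.numeric(grid)
  if (!length(grid)) stop("empty grid")
  reported <- fit_km(data)
  if (any(grid < 0) || any(grid > reported$max_follow_up)) {
    stop("grid outside the follow-up window of the reported data")
  }
  shifted <- fit_km(shift_events_full(data, scheme))
  s_rep <- as.numeric(evaluate_km(reported, grid))
  s_shift <- as.numeric(evaluate_km(shifted, grid))
  observation_band(grid, pmin(s_rep, s_shift), pmax(s_rep, s_shift))
}

#' @export
print.observation_band <- function(x, ...) {
  cat(sprintf(
    "Observation variability band: %d grid points on [%.3g, %.3g]\n",
    length(x$grid), min(x$grid), max(x$grid)
  ))
  cat(sprintf("  mean width %.4g\n", mean(x$hi - x$lo)))
  invisible(x)
}
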