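#' Kaplan-Meier estimation of the event-free curve
#'
#' Fits the product-limit estimator to a time/event dataset. Ties between
#' events and censorings at the same time are resolved events-first (subjects
#' censored at t are still at risk at t), and the fitted curve is
#' right-continuous: the drop occurs *at* the event time.
#'
#' @param data a [survival_data()] object or coercible data frame; must be
#'   non-empty with non-negative times.
#' @return An object of class `"km_curve"` with components
#'   \describe{
#'     \item{event_times}{strictly increasing distinct times with >= 1 event}
#'     \item{surv_prob}{event-free probability just after each event time}
#'     \item{n_at_risk, n_events}{risk-set size and event count per event time}
#'     \item{max_follow_up}{largest time (event or censoring) in the data}
#'     \item{data}{the fitted dataset (needed for observation-shifted refits)}
#'   }
#' @seealso [evaluate_km()], [median_time()], [otu_band()]
#' @examples
#' km <- fit_km(survival_data(c(1, 2, 3, 4), c(1, 0, 1, 1)))
#' evaluate_km(km, c(0, 1, 3.5))
#' @export
fit_km <- function(data) {
  data <- as_survival_data(data)
  if (nrow(data) == 0L) stop("empty dataset")
  fit <- survival::survfit(
    survival::Surv(time, event) ~ 1,
    data = data, conf.type = "none"
  )
  keep <- fit$n.event > 0
  structure(
    list(
      event_times = fit$time[keep],
      surv_prob = fit$surv[keep],
      n_at_risk = as.integer(fit$n.risk[keep]),
      n_events = as.integer(fit$n.event[keep]),
      max_follow_up = max(data$time),
      n = nrow(data),
      label = attr(data, "label"),
      data = data
    ),
    class = "km_curve"
  )
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Step-function evaluation with the last value carried forward
#' (right-continuous: at an event time the post-drop value is returned).
#' Times beyond the maximum follow-up return the last value and are flagged
#' in the `"extrapolated"` attribute so downstream metrics can truncate
#' their grids.
#'
#' @param curve a `"km_curve"` object.
#' @param t numeric vector of non-negative evaluation times.
#' @return Numeric vector of event-free probabilities, with a logical
#'   attribute `"extrapolated"` marking times beyond follow-up.
#' @export
evaluate_km <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  t <- as.numeric(t)
  if (any(t < 0)) stop("negative time")
  s <- c(1, curve$surv_prob)[findInterval(t, curve$event_times) + 1L]
  attr(s, "extrapolated") <- t > curve$max_follow_up
  s
}

#' Median survival time of a fitted curve
#'
#' The smallest event time at which the event-free probability drops to 0.5
#' or below; `NA` when the curve never reaches 0.5 (e.g. heavy censoring).
#'
#' @param curve a `"km_curve"` object.
#' @return A single time in months, or `NA_real_`.
#' @export
median_time <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  i <- which(curve$surv_prob <= 0.5)
  if (!length(i)) {
    return(NA_real_)
  }
  curve$event_times[min(i)]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf(
    "Kaplan-Meier curve%s: n = %d, %d event times, max follow-up %.3g months\n",
    if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
    x$n, length(x$event_times), x$max_follow_up
  ))
  med <- median_time(x)
  cat(
    if (is.na(med)) {
      "  median: not reached\n"
    } else {
      sprintf("  median: %.4g months\n", med)
    }
  )
  invisible(x)
}

#' @export
plot.km_curve <- function(x, add = FALSE, xlab = "Time (months)",
                          ylab = "Event-free probability", col = "black",
                          lwd = 1.5, ...) {
  tt <- c(0, x$event_times, x$max_follow_up)
  ss <- c(1, x$surv_prob, x$surv_prob[length(x$surv_prob)])
  if (!length(x$event_times)) {
    tt <- c(0, x$max_follow_up)
    ss <- c(1, 1)
  }
  if (!add) {
    graphics::plot(tt, ss,
      type = "s", ylim = c(0, 1), xlab = xlab, ylab = ylab,
      col = col, lwd = lwd, ...
    )
  } else {
    graphics::lines(tt, ss, type = "s", col = col, lwd = lwd, ...)
  }
  invisible(x)
}
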