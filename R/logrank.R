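#' Fleming-Harrington weights
#'
#' The FH(rho, gamma) family weights each risk set by
#' `S(t-)^rho * (1 - S(t-))^gamma`, where `S` is the pooled Kaplan-Meier
#' estimate evaluated at the left limit of the event time. `FH(0,0)` is the
#' classical unweighted log-rank; `FH(1,0)` emphasises early differences,
#' `FH(1,1)` mid-study differences and `FH(0,1)` late differences.
#'
#' @param rho,gamma non-negative exponents.
#' @return An object of class `"fh_weights"`.
#' @export
fh_weights <- function(rho = 0, gamma = 0) {
  if (rho < 0 || gamma < 0) stop("rho and gamma must be >= 0")
  structure(list(rho = rho, gamma = gamma), class = "fh_weights")
}

#' @export
print.fh_weights <- function(x, ...) {
  cat(sprintf("FH(%g, %g) weights\n", x$rho, x$gamma))
  invisible(x)
}

# Per-event-time risk-set table for the pooled two-sample data.
# Returns distinct pooled event times with: d (pooled events), n (at risk),
# d1/n1 (events / at risk in group a), and s_left (pooled KM at t-).
# Events-first tie convention: a subject censored at t is still at risk at t.
logrank_table <- function(a, b) {
  time <- c(a$time, b$time)
  event <- c(a$event, b$event)
  in_a <- rep(c(TRUE, FALSE), c(nrow(a), nrow(b)))

  dt <- sort(unique(time[event == 1L]))
  if (!length(dt)) stop("no events")

  st <- sort(time)
  st_a <- sort(time[in_a])
  n <- length(time) - findInterval(dt, st, left.open = TRUE)
  n1 <- sum(in_a) - findInterval(dt, st_a, left.open = TRUE)
  d <- tabulate(match(time[event == 1L], dt), length(dt))
  d1 <- tabulate(match(time[event == 1L & in_a], dt), length(dt))

  km <- cumprod(1 - d / n)
  s_left <- c(1, km[-length(km)])
  list(t = dt, d = d, n = n, d1 = d1, n1 = n1, s_left = s_left)
}

fh_statistic <- function(tab, rho, gamma) {
  w <- tab$s_left^rho * (1 - tab$s_left)^gamma
  u <- sum(w * (tab$d1 - tab$d * tab$n1 / tab$n))
  vterm <- ifelse(
    tab$n > 1,
    tab$d * (tab$n1 / tab$n) * (1 - tab$n1 / tab$n) *
      (tab$n - tab$d) / (tab$n - 1),
    0
  )
  v <- sum(w^2 * vterm)
  list(u = u, v = v)
}

#' Two-sample Fleming-Harrington weighted log-rank test
#'
#' At each distinct pooled event time the observed number of events in the
#' first group is compared with its expectation under the null of equal
#' survival (hypergeometric mean and variance of the risk set), and the
#' weighted differences are summed. The standardized statistic
#' `z = U / sqrt(V)` is referred to the normal distribution (two-sided).
#'
#' @param a,b survival datasets (the two groups); both non-empty, with at
#'   least one event in the pooled data.
#' @param w an [fh_weights()] object (default FH(0,0), the plain log-rank).
#' @return An object of class `"logrank_result"` with components `z`,
#'   `chi2` (= z^2), `p` (two-sided), and `weights`.
#' @examples
#' a <- survival_data(c(6, 7, 10, 15, 19, 25), c(1, 1, 1, 0, 0, 0))
#' b <- survival_data(c(1, 3, 4, 5), c(1, 1, 1, 1))
#' weighted_logrank(a, b)
#' @export
weighted_logrank <- function(a, b, w = fh_weights(0, 0)) {
  a <- as_survival_data(a)
  b <- as_survival_data(b)
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty dataset")
  stopifnot(inherits(w, "fh_weights"))
  tab <- logrank_table(a, b)
  st <- fh_statistic(tab, w$rho, w$gamma)
  if (st$v <= 0) {
    warning("zero variance in weighted log-rank; z set to 0")
    z <- 0
  } else {
    z <- st$u / sqrt(st$v)
  }
  p <- 2 * stats::pnorm(-abs(z))
  structure(
    list(z = z, chi2 = z^2, p = p, weights = w),
    class = "logrank_result"
  )
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf(
    "Weighted log-rank FH(%g, %g): z = %.4g, chi2 = %.4g, p = %.4g\n",
    x$weights$rho, x$weights$gamma, x$z, x$chi2, x$p
  ))
  invisible(x)
}

#' MaxCombo combination of weighted log-rank tests
#'
#' Runs the four Fleming-Harrington tests FH(0,0), FH(1,0), FH(1,1) and
#' FH(0,1), selects the one with the largest absolute z-score (ties broken
#' in that listed order), and applies a Bonferroni correction for the four
#' tests: `p_adjusted = min(1, 4 * p_raw)`. This retains power against
#' non-proportional-hazards alternatives (early, mid or late separation,
#' crossing curves) where the plain log-rank loses power.
#'
#' @inheritParams weighted_logrank
#' @return An object of class `"maxcombo_result"`: list with `per_test`
#'   (the four `"logrank_result"`s), `selected` (index 1-4), `p_raw` and
#'   `p_adjusted`.
#' @export
maxcombo <- function(a, b) {
  a <- as_survival_data(a)
  b <- as_survival_data(b)
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty dataset")
  tab <- logrank_table(a, b)
  combos <- list(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  per <- lapply(combos, function(rg) {
    st <- fh_statistic(tab, rg[1], rg[2])
    z <- if (st$v <= 0) 0 else st$u / sqrt(st$v)
    structure(
      list(
        z = z, chi2 = z^2, p = 2 * stats::pnorm(-abs(z)),
        weights = fh_weights(rg[1], rg[2])
      ),
      class = "logrank_result"
    )
  })
  zs <- vapply(per, `[[`, numeric(1), "z")
  sel <- which.max(abs(zs)) # which.max takes the first maximum: listed order
  p_raw <- per[[sel]]$p
  structure(
    list(
      per_test = per, selected = sel, p_raw = p_raw,
      p_adjusted = min(1, 4 * p_raw)
    ),
    class = "maxcombo_result"
  )
}

#' @export
print.maxcombo_result <- function(x, ...) {
  lab <- vapply(x$per_test, function(r) {
    sprintf("FH(%g,%g)", r$weights$rho, r$weights$gamma)
  }, character(1))
  cat("MaxCombo weighted log-rank combination\n")
  for (i in seq_along(x$per_test)) {
    cat(sprintf(
      "  %s%s z = %8.4g  p = %.4g\n", lab[i],
      if (i == x$selected) " *" else "  ", x$per_test[[i]]$z,
      x$per_test[[i]]$p
    ))
  }
  cat(sprintf(
    "  selected %s: p_raw = %.4g, Bonferroni p_adjusted = %.4g\n",
    lab[x$selected], x$p_raw, x$p_adjusted
  ))
  invisible(x)
}

#' Proportional-hazards diagnostic for two groups
#'
#' Fits a Cox proportional-hazards regression on the group indicator and
#' applies the scaled-Schoenfeld-residual score test of proportionality.
#' Used per bootstrap iteration for exploratory purposes: a high violation
#' ratio warns that plain log-rank metrics may be unreliable.
#'
#' When the fit is degenerate (a group with fewer than two events, or a
#' monotone-likelihood failure) the result is flagged `evaluable = FALSE`
#' and `met = TRUE` (no evidence against proportionality).
#'
#' @inheritParams weighted_logrank
#' @param alpha significance level for the `met` flag (default 0.05).
#' @return An object of class `"ph_check"`: list with `p`, `met`
#'   (`p >= alpha`), and `evaluable`.
#' @export
check_ph <- function(a, b, alpha = 0.05) {
  a <- as_survival_data(a)
  b <- as_survival_data(b)
  if (sum(a$event) < 2L || sum(b$event) < 2L) {
    return(structure(
      list(p = NA_real_, met = TRUE, evaluable = FALSE),
      class = "ph_check"
    ))
  }
  d <- data.frame(
    time = c(a$time, b$time),
    event = c(a$event, b$event),
    grp = rep(c(0L, 1L), c(nrow(a), nrow(b)))
  )
  p <- tryCatch(
    {
      fit <- suppressWarnings(
        survival::coxph(survival::Surv(time, event) ~ grp, data = d)
      )
      zph <- survival::cox.zph(fit)
      unname(zph$table["grp", "p"])
    },
    error = function(e) NA_real_
  )
  if (is.na(p)) {
    return(structure(
      list(p = NA_real_, met = TRUE, evaluable = FALSE),
      class = "ph_check"
    ))
  }
  structure(
    list(p = p, met = p >= alpha, evaluable = TRUE),
    class = "ph_check"
  )
}

#' @export
print.ph_check <- function(x, ...) {
  if (!x$evaluable) {
    cat("Proportional-hazards check: not evaluable (degenerate fit)\n")
  } else {
    cat(sprintf(
      "Proportional-hazards check: p = %.4g (%s)\n", x$p,
      if (x$met) "assumption met" else "violated"
    ))
  }
  invisible(x)
}
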