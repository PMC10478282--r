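METHOD_NAMES <- c(
  "raw_coverage", "juncture",
  "boot_logrank", "boot_logrank_otu",
  "boot_maxcombo", "boot_maxcombo_otu"
)

METHOD_LABELS <- c(
  raw_coverage = "Raw coverage",
  juncture = "Juncture",
  boot_logrank = "Bootstrapped log-rank (no OTU)",
  boot_logrank_otu = "Bootstrapped log-rank (with OTU)",
  boot_maxcombo = "Bootstrapped MaxCombo (no OTU)",
  boot_maxcombo_otu = "Bootstrapped MaxCombo (with OTU)"
)

#' Validate time-to-event model predictions against an observed cohort
#'
#' Runs the six empirical validation methods comparing a large pool of
#' exact predicted times-to-event against an observed time/event cohort:
#' two interval-based metrics (raw coverage of the observed Kaplan-Meier
#' curve by the bootstrapped 95% prediction interval, and the juncture of
#' that interval with the observation variability band) and four
#' bootstrapped-test metrics (log-rank and MaxCombo, each with and without
#' per-patient random observation-time shifts). Every metric is a
#' percentage in \[0, 100\]; each is compared to the same acceptance
#' `threshold` (default 80%) and the model is "validated" by a method when
#' the metric reaches it.
#'
#' @param pool simulated pool of predicted times-to-event (all events),
#'   typically much larger than the observed cohort.
#' @param observed observed cohort (time/event, months).
#' @param otu_width observation time uncertainty: the inter-visit delay in
#'   months (default 2).
#' @param n_iter bootstrap iterations for both the prediction interval and
#'   the test-based metrics (default 5000).
#' @param alpha significance level of the bootstrapped tests (default 0.05).
#' @param threshold acceptance threshold in percent (default 80).
#' @param sample_size per-iteration subsample size; defaults to the
#'   observed cohort size.
#' @param grid_points number of grid points for the interval metrics
#'   (default 1000; midpoint grid, see [time_grid()]).
#' @param seed master seed; every source of randomness in the run descends
#'   from it, so identical seed and config reproduce the report exactly.
#' @param methods subset of `"raw_coverage"`, `"juncture"`,
#'   `"boot_logrank"`, `"boot_logrank_otu"`, `"boot_maxcombo"`,
#'   `"boot_maxcombo_otu"` to compute (default: all six).
#' @param check_ph run the proportional-hazards diagnostic inside the
#'   bootstrap loops?
#' @return An object of class `"tte_validation"`: list with `metrics`
#'   (data frame: method, label, value, validated, ph_violation),
#'   `observed_km`, `pi` (the prediction interval), `band`, `boot`
#'   (the `"boot_ratio"` objects), `config`, and `inputs` (fingerprints).
#' @examples
#' pool <- simulate_model_pool(5000, event_dist("exponential", rate = 0.08))
#' trial <- simulate_trial(scenario_presets()$null)
#' v <- tte_validate(pool, trial$reported, n_iter = 100, seed = 1)
#' print(v)
#' @export
tte_validate <- function(pool, observed, otu_width = 2, n_iter = 5000L,
                         alpha = 0.05, threshold = 80, sample_size = NULL,
                         grid_points = 1000L, seed = NULL,
                         methods = METHOD_NAMES, check_ph = TRUE) {
  pool <- as_survival_data(pool)
  observed <- as_survival_data(observed)
  methods <- match.arg(methods, METHOD_NAMES, several.ok = TRUE)
  if (!(threshold > 0 && threshold <= 100)) stop("threshold must be in (0, 100]")
  if (is.null(sample_size)) sample_size <- nrow(observed)
  scheme <- observation_scheme(otu_width)

  if (!is.null(seed)) set.seed(as.integer(seed))
  # one sub-seed per component so methods can be subset without
  # perturbing each other's random streams
  sub_seed <- as.list(sample.int(.Machine$integer.max - 1L, 5L))
  names(sub_seed) <- c("pi", "lr", "lr_otu", "mc", "mc_otu")

  obs_km <- fit_km(observed)
  t_end <- min(obs_km$max_follow_up, max(pool$time))
  grid <- time_grid(t_end, grid_points)

  value <- stats::setNames(rep(NA_real_, 6), METHOD_NAMES)
  phv <- stats::setNames(rep(NA_real_, 6), METHOD_NAMES)
  pi95 <- band <- NULL
  boot <- list()

  need_pi <- any(c("raw_coverage", "juncture") %in% methods)
  if (need_pi) {
    set.seed(sub_seed$pi)
    pi95 <- build_prediction_interval(pool, sample_size, n_iter, grid)
  }
  if ("raw_coverage" %in% methods) {
    value["raw_coverage"] <- raw_coverage(obs_km, pi95)
  }
  if ("juncture" %in% methods) {
    band <- otu_band(observed, scheme, grid)
    value["juncture"] <- juncture(band, pi95)
  }

  boot_spec <- list(
    boot_logrank = list(test = "logrank", otu = FALSE, seed = sub_seed$lr),
    boot_logrank_otu = list(test = "logrank", otu = TRUE, seed = sub_seed$lr_otu),
    boot_maxcombo = list(test = "maxcombo", otu = FALSE, seed = sub_seed$mc),
    boot_maxcombo_otu = list(test = "maxcombo", otu = TRUE, seed = sub_seed$mc_otu)
  )
  for (m in intersect(names(boot_spec), methods)) {
    sp <- boot_spec[[m]]
    br <- bootstrap_test_ratio(pool, observed,
      test = sp$test, with_otu = sp$otu, scheme = scheme,
      n_iter = n_iter, alpha = alpha, threshold = threshold / 100,
      sample_size = sample_size, seed = sp$seed, check_ph = check_ph
    )
    boot[[m]] <- br
    value[m] <- 100 * br$ratio_nonsig
    phv[m] <- 100 * br$ratio_ph_violated
  }

  metrics <- data.frame(
    method = METHOD_NAMES,
    label = unname(METHOD_LABELS[METHOD_NAMES]),
    value = unname(value),
    validated = ifelse(is.na(value), NA, unname(value) >= threshold),
    ph_violation = unname(phv),
    stringsAsFactors = FALSE
  )
  metrics <- metrics[metrics$method %in% methods, , drop = FALSE]
  rownames(metrics) <- NULL

  structure(
    list(
      metrics = metrics,
      observed_km = obs_km, pi = pi95, band = band, boot = boot,
      config = list(
        otu_width = otu_width, n_iter = n_iter, alpha = alpha,
        threshold = threshold, sample_size = sample_size,
        grid_points = as.integer(grid_points), t_end = t_end, seed = seed
      ),
      inputs = list(
        pool = input_fingerprint(pool),
        observed = input_fingerprint(observed)
      ),
      created = format(Sys.time(), tz = "UTC", usetz = TRUE)
    ),
    class = "tte_validation"
  )
}

input_fingerprint <- function(data) {
  list(
    n = nrow(data), n_events = sum(data$event == 1L),
    checksum = sprintf("%.6f", sum(data$time) + sum(data$event))
  )
}

#' @export
print.tte_validation <- function(x, digits = 4, ...) {
  cat("Time-to-event model validation\n")
  cat(sprintf(
    "  pool: %d simulated endpoints; observed: %d records (%d events)\n",
    x$inputs$pool$n, x$inputs$observed$n, x$inputs$observed$n_events
  ))
  cat(sprintf(
    "  OTU %g months, %d iterations, alpha %g, threshold %g%%\n\n",
    x$config$otu_width, x$config$n_iter, x$config$alpha, x$config$threshold
  ))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf(
      "  %-34s %7.*f%%  %s%s\n", m$label[i], 2, m$value[i],
      if (isTRUE(m$validated[i])) "validated" else "NOT validated",
      if (!is.na(m$ph_violation[i])) {
        sprintf("  (PH violated %.*f%%)", 2, m$ph_violation[i])
      } else {
        ""
      }
    ))
  }
  cat(sprintf(
    "\n  overall: %d of %d methods validated\n",
    sum(m$validated, na.rm = TRUE), nrow(m)
  ))
  invisible(x)
}

#' @export
summary.tte_validation <- function(object, ...) {
  print(object, ...)
  cat("\nDetails\n")
  cat(sprintf(
    "  observation window [0, %.4g] months, %d grid points\n",
    object$config$t_end, object$config$grid_points
  ))
  med <- median_time(object$observed_km)
  cat(sprintf(
    "  observed median: %s\n",
    if (is.na(med)) "not reached" else sprintf("%.4g months", med)
  ))
  for (m in names(object$boot)) {
    br <- object$boot[[m]]
    if (br$n_not_evaluable > 0) {
      cat(sprintf(
        "  %s: %d iterations not evaluable\n",
        METHOD_LABELS[[m]], br$n_not_evaluable
      ))
    }
  }
  invisible(object)
}

#' Plot a validation run
#'
#' Draws the observed Kaplan-Meier curve with the bootstrapped 95%
#' prediction interval of the simulated curve (green band) and, optionally,
#' the observation variability band.
#'
#' @param x a `"tte_validation"` object (must include the interval
#'   metrics).
#' @param show_band overlay the observation variability band?
#' @param ... passed to [plot.km_curve()].
#' @return `x`, invisibly.
#' @export
plot.tte_validation <- function(x, show_band = TRUE, ...) {
  if (is.null(x$pi)) stop("no prediction interval in this validation run")
  pi95 <- x$pi
  graphics::plot(NA,
    xlim = c(0, x$config$t_end), ylim = c(0, 1),
    xlab = "Time (months)", ylab = "Event-free probability", ...
  )
  graphics::polygon(c(pi95$grid, rev(pi95$grid)), c(pi95$lo, rev(pi95$hi)),
    col = grDevices::adjustcolor("forestgreen", 0.35), border = NA
  )
  if (show_band && !is.null(x$band)) {
    graphics::lines(x$band$grid, x$band$lo, lty = 3, col = "steelblue")
    graphics::lines(x$band$grid, x$band$hi, lty = 3, col = "steelblue")
  }
  plot(x$observed_km, add = TRUE, col = "black", lwd = 2)
  graphics::legend("topright",
    legend = c("observed KM", "95% prediction interval"),
    col = c("black", "forestgreen"), lwd = c(2, 8), bty = "n"
  )
  invisible(x)
}

#' Compare validation runs method-by-method
#'
#' Signed pairwise differences (in percentage points) between the metric
#' values of two or more validation reports sharing the same method list —
#' e.g. the full cohort against mutation-defined subsets.
#'
#' @param ... two or more `"tte_validation"` objects.
#' @param labels optional run labels (default `run1`, `run2`, ...).
#' @return A data frame of class `"tte_comparison"`: one row per method,
#'   one `value_<label>` column per run and one signed
#'   `diff_<a>_minus_<b>` column per ordered pair.
#' @export
compare_validations <- function(..., labels = NULL) {
  runs <- list(...)
  if (length(runs) == 1L && is.list(runs[[1]]) &&
    !inherits(runs[[1]], "tte_validation")) {
    runs <- runs[[1]]
  }
  if (length(runs) < 2L) stop("need at least two validation reports")
  if (!all(vapply(runs, inherits, logical(1), "tte_validation"))) {
    stop("all inputs must be tte_validation objects")
  }
  if (is.null(labels)) labels <- paste0("run", seq_along(runs))
  meth <- runs[[1]]$metrics$method
  for (r in runs[-1]) {
    if (!identical(r$metrics$method, meth)) stop("mismatched method lists")
  }
  out <- data.frame(
    method = meth,
    label = runs[[1]]$metrics$label,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(runs)) {
    out[[paste0("value_", labels[i])]] <- runs[[i]]$metrics$value
  }
  for (i in seq_along(runs)) {
    for (j in seq_along(runs)) {
      if (i < j) {
        out[[sprintf("diff_%s_minus_%s", labels[i], labels[j])]] <-
          runs[[i]]$metrics$value - runs[[j]]$metrics$value
      }
    }
  }
  class(out) <- c("tte_comparison", "data.frame")
  out
}

#' Write a validation report to JSON
#'
#' Machine-readable twin of the printed table: metric values, verdicts,
#' PH-violation ratios, the configuration echo and input fingerprints.
#'
#' @param x a `"tte_validation"` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_validation_json <- function(x, path) {
  stopifnot(inherits(x, "tte_validation"))
  payload <- list(
    schema = "tteval/validation-report/v1",
    created = x$created,
    config = x$config,
    inputs = x$inputs,
    methods = lapply(seq_len(nrow(x$metrics)), function(i) {
      row <- x$metrics[i, ]
      list(
        method = row$method, label = row$label,
        metric_value_pct = row$value, validated = row$validated,
        ph_violation_pct = if (is.na(row$ph_violation)) NULL else row$ph_violation
      )
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
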