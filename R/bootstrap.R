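#' Bootstrapped ratio of non-significant survival tests
#'
#' The test-based validation metrics: at each iteration a subsample of the
#' simulated pool, of the size of the observed cohort, is compared to the
#' observed data with a log-rank or MaxCombo test. The statistic of interest
#' is the fraction of iterations whose test is *not* significant at `alpha`
#' — the higher the ratio, the closer the model predictions are to the
#' observations. Restricting each comparison to a clinical-trial-sized
#' subsample controls the excess statistical power a very large simulated
#' population would otherwise grant.
#'
#' With `with_otu = TRUE` the observed cohort is replaced, at every
#' iteration, by a fresh random OTU shift ([sample_otu_shift()]), modelling
#' the unknown true event times. The proportional-hazards assumption is
#' checked on the same pair at each iteration for exploratory purposes.
#'
#' A master `seed` spawns one sub-seed per iteration, drawn before any
#' iteration runs, and the pool subsample is drawn before the OTU shift
#' within an iteration. Two runs with the same seed therefore share their
#' subsample draws whether or not OTU is enabled — paired comparisons for
#' free — and identical seed plus config gives a bit-identical result.
#'
#' @param pool simulated pool of predicted times-to-event.
#' @param observed observed cohort (time/event); at least one event.
#' @param test `"logrank"` (plain FH(0,0)) or `"maxcombo"` (which uses the
#'   Bonferroni-adjusted p-value).
#' @param with_otu apply a fresh random observation-time shift to the
#'   observed cohort at each iteration?
#' @param scheme [observation_scheme()]; required when `with_otu = TRUE`.
#' @param n_iter bootstrap iterations (default 5000).
#' @param alpha significance level (default 0.05).
#' @param threshold validation acceptance ratio in `[0, 1]` (default 0.80).
#' @param sample_size per-iteration subsample size; defaults to the
#'   observed cohort size.
#' @param seed integer master seed; `NULL` uses the current RNG state.
#' @param check_ph run the proportional-hazards diagnostic each iteration?
#' @param replace subsample the pool with replacement?
#' @return An object of class `"boot_ratio"`: list with `ratio_nonsig`,
#'   `ratio_ph_violated`, `validated`, `n_evaluable`, `n_not_evaluable`,
#'   and `per_iteration` (data frame with `p`, `selected`, `ph_met`,
#'   `evaluable`).
#' @examples
#' pool <- survival_data(stats::rexp(5000, 0.08))
#' obs <- survival_data(stats::rexp(60, 0.08))
#' bootstrap_test_ratio(pool, obs, n_iter = 50, seed = 1, check_ph = FALSE)
#' @export
bootstrap_test_ratio <- function(pool, observed,
                                 test = c("logrank", "maxcombo"),
                                 with_otu = FALSE, scheme = NULL,
                                 n_iter = 5000L, alpha = 0.05,
                                 threshold = 0.80, sample_size = NULL,
                                 seed = NULL, check_ph = TRUE,
                                 replace = FALSE) {
  test <- match.arg(test)
  pool <- as_survival_data(pool)
  observed <- as_survival_data(observed)
  if (sum(observed$event) < 1L) stop("observed cohort has no events")
  if (with_otu && !inherits(scheme, "observation_scheme")) {
    stop("with_otu = TRUE requires an observation_scheme")
  }
  n_iter <- as.integer(n_iter)
  if (n_iter < 1L) stop("n_iter must be >= 1")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  if (is.null(sample_size)) sample_size <- nrow(observed)
  sample_size <- as.integer(sample_size)
  if (!replace && nrow(pool) < sample_size) stop("pool smaller than sample_size")

  if (!is.null(seed)) set.seed(as.integer(seed))
  iter_seeds <- sample.int(.Machine$integer.max - 1L, n_iter)

  p <- numeric(n_iter)
  selected <- rep(NA_integer_, n_iter)
  ph_met <- rep(NA, n_iter)
  evaluable <- rep(TRUE, n_iter)

  for (i in seq_len(n_iter)) {
    set.seed(iter_seeds[i])
    idx <- sample.int(nrow(pool), sample_size, replace = replace)
    sim <- survival_data(pool$time[idx], pool$event[idx], label = "simulated")
    obs_i <- if (with_otu) sample_otu_shift(observed, scheme) else observed
    res <- tryCatch(
      {
        if (test == "logrank") {
          r <- suppressWarnings(weighted_logrank(sim, obs_i))
          list(p = r$p, selected = NA_integer_)
        } else {
          r <- maxcombo(sim, obs_i)
          list(p = r$p_adjusted, selected = r$selected)
        }
      },
      error = function(e) NULL
    )
    if (is.null(res)) {
      evaluable[i] <- FALSE
      p[i] <- NA_real_
      next
    }
    p[i] <- res$p
    selected[i] <- res$selected
    if (check_ph) {
      ph <- check_ph(sim, obs_i, alpha = alpha)
      ph_met[i] <- if (ph$evaluable) ph$met else NA
    }
  }

  n_eval <- sum(evaluable)
  if (n_eval == 0L) stop("no evaluable bootstrap iterations")
  if (n_eval < n_iter) {
    message(sprintf(
      "%d of %d iterations not evaluable; excluded from the denominator",
      n_iter - n_eval, n_iter
    ))
  }
  ratio_nonsig <- mean(p[evaluable] >= alpha)
  ph_eval <- ph_met[evaluable & !is.na(ph_met)]
  ratio_ph_violated <- if (length(ph_eval)) mean(!ph_eval) else NA_real_

  structure(
    list(
      test = test, with_otu = with_otu,
      ratio_nonsig = ratio_nonsig,
      ratio_ph_violated = ratio_ph_violated,
      validated = verdict(100 * ratio_nonsig, 100 * threshold),
      n_iter = n_iter, n_evaluable = n_eval,
      n_not_evaluable = n_iter - n_eval,
      alpha = alpha, threshold = threshold,
      sample_size = sample_size, seed = seed,
      per_iteration = data.frame(
        p = p, selected = selected, ph_met = ph_met, evaluable = evaluable
      )
    ),
    class = "boot_ratio"
  )
}

#' @export
print.boot_ratio <- function(x, ...) {
  cat(sprintf(
    "Bootstrapped %s%s: %d iterations (%d evaluable)\n",
    if (x$test == "logrank") "log-rank" else "MaxCombo",
    if (x$with_otu) " with OTU" else "", x$n_iter, x$n_evaluable
  ))
  cat(sprintf(
    "  ratio of non-significant tests at alpha = %g: %.4g%% (threshold %g%%): %s\n",
    x$alpha, 100 * x$ratio_nonsig, 100 * x$threshold,
    if (x$validated) "validated" else "NOT validated"
  ))
  if (!is.na(x$ratio_ph_violated)) {
    cat(sprintf(
      "  PH assumption violated in %.4g%% of evaluable iterations\n",
      100 * x$ratio_ph_violated
    ))
  }
  invisible(x)
}

#' Running ratio of non-significant tests
#'
#' Cumulative ratio after k evaluable iterations, k = 1..n, used to judge
#' how many bootstrap iterations are needed before the metric stabilizes.
#'
#' @param result a `"boot_ratio"` with `per_iteration` retained.
#' @return Numeric vector of running ratios (one per evaluable iteration).
#' @export
convergence_trace <- function(result) {
  stopifnot(inherits(result, "boot_ratio"))
  pi_tab <- result$per_iteration
  p <- pi_tab$p[pi_tab$evaluable]
  cumsum(p >= result$alpha) / seq_along(p)
}

#' Validation verdict against a threshold
#'
#' Shared acceptance rule for all validation metrics: a metric value (in
#' percent) validates the model when it reaches the threshold. The boundary
#' counts as validated (closed comparison).
#'
#' @param metric_value metric in `[0, 100]`.
#' @param threshold threshold in `[0, 100]` (default 80).
#' @return Logical.
#' @export
verdict <- function(metric_value, threshold = 80) {
  stopifnot(
    metric_value >= 0, metric_value <= 100,
    threshold >= 0, threshold <= 100
  )
  metric_value >= threshold
}
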