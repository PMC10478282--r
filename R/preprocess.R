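DAYS_PER_MONTH <- 30.4375

#' Derive time-to-progression from PFS and OS event lists
#'
#' A deterministic tumor-progression model predicts time-to-progression
#' (TTP), which censors out death, while published trial curves report
#' progression-free survival (PFS: progression or death) and overall
#' survival (OS: death). Under the assumption that a patient who died
#' before progression carries the same time in the PFS and OS lists, TTP
#' events are recovered by (1) dropping censored PFS records, then (2)
#' removing every PFS event that matches an OS event within a small
#' tolerance (those are deaths, not progressions). The remaining PFS events
#' form the TTP dataset.
#'
#' Matching is one-to-one and greedy: PFS events are processed in ascending
#' time and each is matched to the closest not-yet-used OS event within
#' tolerance (distance ties go to the earliest OS time). Cases where more
#' than one OS event was eligible are counted as ambiguous in the report
#' rather than resolved silently.
#'
#' @param pfs PFS dataset (time/event); censored records are removed and
#'   counted.
#' @param os OS dataset; only its event (death) times participate in
#'   matching.
#' @param tolerance_days maximum PFS-OS discrepancy treated as equality,
#'   in days (default 2; months are converted at 30.4375 days/month).
#' @return A list with components `ttp` (the derived `"survival_data"`, all
#'   events) and `report` (class `"ttp_derivation"`): counts
#'   `n_input_pfs`, `n_censored_removed`, `n_death_removed`, `n_ttp`
#'   (which always sum to the input size), the `matched_pairs` data frame,
#'   and `n_ambiguous`.
#' @examples
#' pfs <- survival_data(c(3, 5, 9), c(1, 1, 1))
#' os <- survival_data(c(5.02, 12), c(1, 1))
#' derive_ttp(pfs, os)$ttp$time # 3 and 9: the 5-month PFS event was a death
#' @export
derive_ttp <- function(pfs, os, tolerance_days = 2) {
  pfs <- as_survival_data(pfs)
  os <- as_survival_data(os)
  if (nrow(pfs) == 0L) stop("empty dataset")
  tol <- tolerance_days / DAYS_PER_MONTH

  n_input <- nrow(pfs)
  n_censored <- sum(pfs$event == 0L)
  pfs_ev <- sort(pfs$time[pfs$event == 1L])
  os_ev <- sort(os$time[os$event == 1L])
  used <- rep(FALSE, length(os_ev))

  is_death <- rep(FALSE, length(pfs_ev))
  pairs_pfs <- pairs_os <- numeric(0)
  n_ambiguous <- 0L
  for (i in seq_along(pfs_ev)) {
    cand <- which(!used & abs(os_ev - pfs_ev[i]) <= tol)
    if (!length(cand)) next
    if (length(cand) > 1L) n_ambiguous <- n_ambiguous + 1L
    # closest eligible OS event; distance ties -> earliest OS time
    # (os_ev is sorted, so which.min already picks the earliest on a tie)
    j <- cand[which.min(abs(os_ev[cand] - pfs_ev[i]))]
    used[j] <- TRUE
    is_death[i] <- TRUE
    pairs_pfs <- c(pairs_pfs, pfs_ev[i])
    pairs_os <- c(pairs_os, os_ev[j])
  }

  ttp_times <- pfs_ev[!is_death]
  ttp <- survival_data(ttp_times,
    rep(1L, length(ttp_times)),
    label = "derived TTP"
  )
  report <- structure(
    list(
      n_input_pfs = n_input,
      n_censored_removed = n_censored,
      n_death_removed = sum(is_death),
      n_ttp = length(ttp_times),
      n_ambiguous = n_ambiguous,
      tolerance_days = tolerance_days,
      matched_pairs = data.frame(pfs_time = pairs_pfs, os_time = pairs_os)
    ),
    class = "ttp_derivation"
  )
  list(ttp = ttp, report = report)
}

#' @export
print.ttp_derivation <- function(x, ...) {
  cat("TTP derivation from PFS/OS\n")
  cat(sprintf(
    "  %d PFS records: %d censored removed, %d deaths removed, %d TTP events\n",
    x$n_input_pfs, x$n_censored_removed, x$n_death_removed, x$n_ttp
  ))
  cat(sprintf(
    "  matching tolerance %g days; %d ambiguous multi-candidate matches\n",
    x$tolerance_days, x$n_ambiguous
  ))
  invisible(x)
}
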