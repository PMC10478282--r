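#' Construct a labelled time-to-event dataset
#'
#' A survival dataset is the universal input of the package: one row per
#' subject with an elapsed `time` (months, non-negative) and an `event`
#' indicator (1 = event observed, 0 = right-censored). Predicted
#' times-to-event from a deterministic model are stored in the same container
#' with `event = 1` for every record, since a simulated event time is known
#' exactly.
#'
#' @param time numeric vector of non-negative elapsed times, in months.
#' @param event event indicators, coercible to 0/1 (logical accepted).
#'   Defaults to all events.
#' @param label free-text label carried along for printing and reports.
#' @return An object of class `"survival_data"`: a `data.frame` with columns
#'   `time` and `event` and a `label` attribute.
#' @examples
#' survival_data(c(3.1, 5.4, 9.9), c(1, 0, 1), label = "toy cohort")
#' @export
survival_data <- function(time, event = rep(1, length(time)), label = "") {
  time <- as.numeric(time)
  if (anyNA(time)) stop("missing time values")
  if (any(time < 0)) stop("negative time")
  event <- as.integer(event)
  if (length(event) != length(time)) stop("time and event lengths differ")
  if (anyNA(event) || !all(event %in% c(0L, 1L))) {
    stop("event must be 0/1")
  }
  out <- data.frame(time = time, event = event)
  attr(out, "label") <- as.character(label)[1]
  class(out) <- c("survival_data", "data.frame")
  out
}

#' Coerce to a survival dataset
#'
#' Accepts a `survival_data` object or any data frame with `time` and `event`
#' columns.
#'
#' @param x object to coerce.
#' @param label optional label; kept from `x` when already present.
#' @return A `"survival_data"` object.
#' @export
as_survival_data <- function(x, label = NULL) {
  if (inherits(x, "survival_data") && is.null(label)) {
    return(x)
  }
  if (is.numeric(x)) {
    return(survival_data(x, label = if (is.null(label)) "" else label))
  }
  if (!is.data.frame(x)) stop("cannot coerce to survival_data")
  if (!all(c("time", "event") %in% names(x))) {
    stop("data frame must have 'time' and 'event' columns")
  }
  lab <- if (!is.null(label)) label else attr(x, "label")
  survival_data(x$time, x$event, label = if (is.null(lab)) "" else lab)
}

#' @export
print.survival_data <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf(
    "Survival dataset%s: %d records, %d events, %d censored\n",
    if (nzchar(lab)) paste0(" '", lab, "'") else "",
    nrow(x), sum(x$event == 1L), sum(x$event == 0L)
  ))
  if (nrow(x)) {
    cat(sprintf(
      "  time range [%.3g, %.3g] months\n", min(x$time), max(x$time)
    ))
  }
  invisible(x)
}

#' Read a time/event table from CSV
#'
#' The expected dialect is comma-separated with a header row containing
#' `time` (months, `.` decimal) and `event` (0/1) columns, UTF-8 encoded.
#'
#' @param path file path.
#' @param label label attached to the dataset; defaults to the file name.
#' @return A `"survival_data"` object.
#' @export
read_tte_csv <- function(path, label = basename(path)) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!all(c("time", "event") %in% names(df))) {
    stop(sprintf("'%s': header must contain 'time' and 'event'", path))
  }
  bad <- which(is.na(suppressWarnings(as.numeric(df$time))))
  if (length(bad)) {
    stop(sprintf("'%s': malformed time value at data row %d", path, bad[1]))
  }
  survival_data(as.numeric(df$time), df$event, label = label)
}

#' Write a time/event table to CSV
#'
#' @param data a `"survival_data"` object (or coercible).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tte_csv <- function(data, path) {
  data <- as_survival_data(data)
  utils::write.csv(data.frame(time = data$time, event = data$event),
    path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
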