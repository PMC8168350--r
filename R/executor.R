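#' Create a CSV-file Executor sink
#'
#' The Executor is the last MAPE-K stage: it receives alerts from the
#' Planner and appends them to a CSV sink, but only while the sink is
#' alive. While the sink is down, alerts are held in arrival order and the
#' held status propagates back to the Planner (back-pressure); held alerts
#' are flushed, in order, as soon as a delivery finds the sink alive again
#' (or via [executor_flush()]).
#'
#' @param path Path of the alerts CSV (header
#'   `window_start_ms,window_end_ms,n_drift,identifiers,decided_at`), or
#'   `NULL` for an in-memory sink.
#' @param alive A function returning `TRUE` while the sink can accept
#'   writes; swap in a probe for real sinks.
#' @return A `driftwatch_executor` environment.
#' @export
executor_csv <- function(path = NULL, alive = function() TRUE) {
  stopifnot(is.function(alive))
  ex <- new.env(parent = emptyenv())
  ex$path <- path
  ex$alive_fn <- alive
  ex$queue <- list()
  ex$delivered <- list()
  if (!is.null(path)) {
    cat("window_start_ms,window_end_ms,n_drift,identifiers,decided_at\n",
        file = path)
  }
  class(ex) <- "driftwatch_executor"
  ex
}

#' Is the Executor's sink alive?
#' @param ex A `driftwatch_executor`.
#' @return Logical.
#' @export
executor_alive <- function(ex) {
  stopifnot(inherits(ex, "driftwatch_executor"))
  isTRUE(ex$alive_fn())
}

alert_csv_row <- function(alert) {
  paste(
    format(alert$window_start_ms, scientific = FALSE, trim = TRUE),
    format(alert$window_end_ms, scientific = FALSE, trim = TRUE),
    alert$n_drift,
    paste(alert$identifiers, collapse = ";"),
    format(alert$decided_at, "%Y-%m-%d %H:%M:%OS3", tz = "UTC"),
    sep = ","
  )
}

write_alert <- function(ex, alert) {
  if (!is.null(ex$path)) {
    cat(alert_csv_row(alert), "\n", sep = "", file = ex$path, append = TRUE)
  }
  ex$delivered[[length(ex$delivered) + 1L]] <- alert
  invisible(NULL)
}

#' Deliver an alert through the Executor
#'
#' @param ex A `driftwatch_executor`.
#' @param alert A `drift_alert` (see [vote()]).
#' @return `"delivered"` when the alert (and any previously held alerts, in
#'   order) reached the sink, `"held"` when the sink is down or the write
#'   failed and the alert was retained.
#' @export
executor_deliver <- function(ex, alert) {
  stopifnot(inherits(ex, "driftwatch_executor"),
            inherits(alert, "drift_alert"))
  if (!executor_alive(ex)) {
    ex$queue[[length(ex$queue) + 1L]] <- alert
    return("held")
  }
  status <- tryCatch({
    executor_flush(ex)
    write_alert(ex, alert)
    "delivered"
  }, error = function(e) {
    ex$queue[[length(ex$queue) + 1L]] <- alert
    "held"
  })
  status
}

#' Flush alerts held while the sink was down
#'
#' @param ex A `driftwatch_executor`.
#' @return Invisibly, the number of alerts flushed.
#' @export
executor_flush <- function(ex) {
  stopifnot(inherits(ex, "driftwatch_executor"))
  done <- 0L
  while (length(ex$queue) && executor_alive(ex)) {
    alert <- ex$queue[[1L]]
    ex$queue <- ex$queue[-1L]
    write_alert(ex, alert)
    done <- done + 1L
  }
  invisible(done)
}

#' Alerts delivered by an Executor, as a tibble
#'
#' @param ex A `driftwatch_executor`.
#' @return A tibble with one row per delivered alert.
#' @export
executor_alerts <- function(ex) {
  stopifnot(inherits(ex, "driftwatch_executor"))
  alerts_tibble(ex$delivered)
}

alerts_tibble <- function(alerts) {
  if (!length(alerts)) {
    return(tibble::tibble(
      window_start_ms = numeric(0), window_end_ms = numeric(0),
      n_drift = integer(0), identifiers = character(0),
      decided_at = as.POSIXct(character(0), tz = "UTC")
    ))
  }
  tibble::tibble(
    window_start_ms = vapply(alerts, `[[`, numeric(1), "window_start_ms"),
    window_end_ms = vapply(alerts, `[[`, numeric(1), "window_end_ms"),
    n_drift = vapply(alerts, `[[`, integer(1), "n_drift"),
    identifiers = vapply(alerts, function(a) {
      paste(a$identifiers, collapse = ";")
    }, character(1)),
    decided_at = as.POSIXct(
      vapply(alerts, function(a) as.numeric(a$decided_at), numeric(1)),
      origin = "1970-01-01", tz = "UTC")
  )
}

#' @export
print.driftwatch_executor <- function(x, ...) {
  cat("<executor: ", if (is.null(x$path)) "in-memory sink" else x$path,
      ", delivered ", length(x$delivered), ", held ", length(x$queue),
      ">\n", sep = "")
  invisible(x)
}
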