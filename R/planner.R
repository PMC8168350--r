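#' Voting rule of the health-monitor Planner
#'
#' The Planner partitions time into tumbling decision windows and, per
#' window, counts the number of distinct channels (muscles) with at least
#' one positive drift verdict, `n_drift`. An alert fires iff
#' `min_drifts <= n_drift < max_drifts`. The defaults encode the
#' case-study reasoning for an 8-muscle montage: a genuine unilateral
#' problem affects at least 2 muscles, while all 8 drifting at once is the
#' cold-start signature and is ignored.
#'
#' @param min_drifts Inclusive lower bound on drifting channels (default 2).
#' @param max_drifts Exclusive upper bound (default 8).
#' @param decision_window_ms Tumbling window length in ms (default 1000).
#' @return A `planner_rule` list.
#' @export
planner_rule <- function(min_drifts = 2L, max_drifts = 8L,
                         decision_window_ms = 1000) {
  stopifnot(
    is.numeric(min_drifts), is.numeric(max_drifts),
    min_drifts >= 1, min_drifts < max_drifts,
    is.numeric(decision_window_ms), decision_window_ms > 0
  )
  structure(
    list(min_drifts = as.integer(min_drifts),
         max_drifts = as.integer(max_drifts),
         decision_window_ms = as.numeric(decision_window_ms)),
    class = "planner_rule"
  )
}

#' Vote on the prediction records of one decision window
#'
#' @param records Tibble of prediction records falling in one decision
#'   window (see [kb_query_window()]).
#' @param rule A [planner_rule()].
#' @param window_start_ms,window_end_ms Window bounds in stream
#'   milliseconds, recorded on the alert.
#' @param decided_at POSIXct decision time (defaults to the latest
#'   `datetime_analysed` in the window).
#' @return A `drift_alert` (list with `window_start_ms`, `window_end_ms`,
#'   `n_drift`, sorted `identifiers`, `decided_at`) when the rule fires,
#'   otherwise `NULL`.
#' @examples
#' # two distinct drifting muscles -> alert; all eight -> suppressed
#' @export
vote <- function(records, rule = planner_rule(), window_start_ms = 0,
                 window_end_ms = window_start_ms + rule$decision_window_ms,
                 decided_at = NULL) {
  stopifnot(inherits(rule, "planner_rule"))
  drifting <- sort(unique(records$identifier[records$predicted]))
  n_drift <- length(drifting)
  if (n_drift < rule$min_drifts || n_drift >= rule$max_drifts) {
    return(NULL)
  }
  if (is.null(decided_at)) {
    decided_at <- max(records$datetime_analysed)
  }
  structure(
    list(window_start_ms = as.numeric(window_start_ms),
         window_end_ms = as.numeric(window_end_ms),
         n_drift = n_drift,
         identifiers = drifting,
         decided_at = decided_at),
    class = "drift_alert"
  )
}

#' Poll the Knowledge Base for new predictions
#'
#' Returns records analysed strictly after `since`, in analysis order. The
#' returned tibble carries a `cursor` attribute; passing that cursor as
#' `since` on the next call guarantees no record is ever returned twice,
#' even across ties in analysis time. An unreachable Knowledge Base yields
#' an empty result with a warning rather than an error.
#'
#' @param kb A `driftwatch_kb` handle.
#' @param since A POSIXct/numeric time, or the `cursor` attribute of a
#'   previous poll.
#' @return A tibble of records with attribute `cursor`.
#' @export
planner_poll <- function(kb, since = -Inf) {
  recs <- tryCatch(kb_records(kb), error = function(e) {
    warning("knowledge base unavailable: ", conditionMessage(e),
            call. = FALSE)
    NULL
  })
  if (is.null(recs)) {
    out <- tibble::tibble()
    attr(out, "cursor") <- since
    return(out)
  }
  if (inherits(since, "kb_cursor")) {
    out <- recs[recs$id > unclass(since), , drop = FALSE]
  } else {
    if (identical(since, -Inf)) {
      out <- recs
    } else {
      out <- recs[as.numeric(recs$datetime_analysed) >
                    as.numeric(parse_kb_time(since, "since")), ,
                  drop = FALSE]
    }
  }
  out <- dplyr::arrange(out, .data$datetime_analysed, .data$id)
  cursor <- if (nrow(recs)) max(recs$id) else
    if (inherits(since, "kb_cursor")) unclass(since) else 0L
  attr(out, "cursor") <- structure(cursor, class = "kb_cursor")
  out
}

#' Run the Planner over the Knowledge Base
#'
#' Partitions the records into consecutive (tumbling) decision windows of
#' `rule$decision_window_ms` keyed on `datetime_monitored` — so decisions
#' are independent of processing latency — applies [vote()] per window,
#' and forwards fired alerts, in window order, through the Executor (which
#' holds them while its sink is down).
#'
#' @param kb A `driftwatch_kb` handle.
#' @param rule A [planner_rule()].
#' @param executor Optional `driftwatch_executor` to deliver alerts to.
#' @param origin POSIXct stream epoch; window k spans
#'   `[k, k+1) * decision_window_ms` after it. Defaults to the earliest
#'   monitored time in the Knowledge Base.
#' @return A tibble of alerts (one row each), invisibly carrying the list
#'   of `drift_alert` objects as attribute `alerts`.
#' @export
planner_run <- function(kb, rule = planner_rule(), executor = NULL,
                        origin = NULL) {
  stopifnot(inherits(rule, "planner_rule"))
  recs <- planner_poll(kb)
  if (!nrow(recs)) return(alerts_tibble(list()))
  mon <- as.numeric(recs$datetime_monitored)
  if (is.null(origin)) origin <- min(mon)
  rel_ms <- (mon - as.numeric(origin)) * 1000
  win <- floor(rel_ms / rule$decision_window_ms)
  alerts <- list()
  for (k in sort(unique(win))) {
    a <- vote(recs[win == k, , drop = FALSE], rule,
              window_start_ms = k * rule$decision_window_ms,
              window_end_ms = (k + 1) * rule$decision_window_ms)
    if (!is.null(a)) alerts[[length(alerts) + 1L]] <- a
  }
  if (!is.null(executor)) {
    for (a in alerts) executor_deliver(executor, a)
  }
  out <- alerts_tibble(alerts)
  attr(out, "alerts") <- alerts
  out
}

#' @export
print.drift_alert <- function(x, ...) {
  cat("<drift alert> window [", x$window_start_ms, ", ", x$window_end_ms,
      ") ms: ", x$n_drift, " channel(s) drifting (",
      paste(x$identifiers, collapse = ", "), ")\n", sep = "")
  invisible(x)
}
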