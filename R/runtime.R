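#' Create an in-process MAPE-K agent runtime
#'
#' The runtime hosts the four agent roles — Monitors capture and forward
#' samples, Analysers predict and persist, Planners read the Knowledge Base
#' and decide, Executors deliver alerts to a sink — over an in-process
#' message bus that preserves the subscription, availability and
#' back-pressure semantics of a distributed deployment (per-publisher FIFO,
#' delivery only to available subscribers, drops logged).
#'
#' Time is the deterministic stream clock: a sample monitored at
#' `timestamp_ms` is stamped `origin + timestamp_ms`, and analysis adds a
#' fixed latency, so identical inputs replay to identical Knowledge Base
#' contents and alerts.
#'
#' @param kb A Knowledge Base handle from [kb_connect()].
#' @param origin POSIXct stream epoch used to stamp samples.
#' @param analysis_latency_ms Fixed monitored-to-analysed latency, ms.
#' @param log_level `"info"` (lifecycle events) or `"debug"` (every
#'   emit/predict as well).
#' @return A `driftwatch_runtime` environment.
#' @export
runtime <- function(kb = kb_connect("memory"),
                    origin = as.POSIXct("2020-01-01 00:00:00", tz = "UTC"),
                    analysis_latency_ms = 1,
                    log_level = c("info", "debug")) {
  stopifnot(inherits(kb, "driftwatch_kb"))
  rt <- new.env(parent = emptyenv())
  rt$kb <- kb
  rt$origin <- as.numeric(origin)
  rt$latency <- analysis_latency_ms / 1000
  rt$agents <- list()
  rt$subs <- list()          # each: list(subscriber, publisher, reciprocal)
  rt$tasks <- character(0)   # queued retraining tasks (analyser jids)
  rt$log_level <- match.arg(log_level)
  rt$log <- vector("list", 64L)
  rt$log_n <- 0L
  rt$in_predict <- FALSE
  rt$train_in_predict <- 0L  # contract violations: training inside predict
  rt$drops <- 0L
  class(rt) <- "driftwatch_runtime"
  rt
}

log_event <- function(rt, event, ..., level = "info") {
  if (level == "debug" && rt$log_level != "debug") return(invisible(NULL))
  entry <- as.character(jsonlite::toJSON(
    c(list(event = event), list(...)), auto_unbox = TRUE, digits = NA))
  n <- rt$log_n + 1L
  if (n > length(rt$log)) length(rt$log) <- 2L * n
  rt$log[[n]] <- entry
  rt$log_n <- n
  invisible(NULL)
}

#' Structured log of a runtime
#' @param rt A `driftwatch_runtime`.
#' @return Character vector, one JSON object per event.
#' @export
runtime_log <- function(rt) {
  stopifnot(inherits(rt, "driftwatch_runtime"))
  unlist(rt$log[seq_len(rt$log_n)], use.names = FALSE)
}

#' Runtime instrumentation counters
#'
#' `train_in_predict` counts training computations that executed inside the
#' prediction path; the asynchronous-training contract requires it to be 0
#' after any run. `drops` counts samples dropped because the subscribed
#' Analyser was unavailable.
#'
#' @param rt A `driftwatch_runtime`.
#' @return A one-row tibble of counters.
#' @export
runtime_stats <- function(rt) {
  stopifnot(inherits(rt, "driftwatch_runtime"))
  tibble::tibble(
    agents = length(rt$agents),
    subscriptions = length(rt$subs),
    kb_records = kb_count(rt$kb),
    drops = rt$drops,
    pending_tasks = length(rt$tasks),
    train_in_predict = rt$train_in_predict
  )
}

#' Register an agent with the runtime
#'
#' @param rt A `driftwatch_runtime`.
#' @param jid Unique agent name.
#' @param role One of `"monitor"`, `"analyser"`, `"planner"`, `"executor"`.
#' @param identifier For Analysers, the channel the detector is bound to
#'   (defaults to `jid`).
#' @param detector For Analysers, an [adwin()] detector.
#' @param controller For Analysers, a [delta_controller()].
#' @param scale For Analysers, input standardization: `"none"` feeds raw
#'   values; a number is the channel's known noise scale (standard
#'   deviation); `"auto"` estimates the scale from the first
#'   `calibration_samples` values and freezes it. Standardized values have
#'   standard deviation `target_sd`.
#' @param calibration_samples Length of the calibration period for
#'   `scale = "auto"`; calibration samples are persisted with
#'   `predicted = FALSE` and not fed to the detector.
#' @param target_sd Reference noise scale the detector operates at; the
#'   default 0.25 keeps stationary noise at half the Hoeffding sd-1/2
#'   reference so the threshold retains a 2x guard margin.
#' @return The agent's descriptor, invisibly.
#' @export
agent_register <- function(rt, jid, role = c("monitor", "analyser",
                                             "planner", "executor"),
                           identifier = jid, detector = NULL,
                           controller = NULL, scale = "none",
                           calibration_samples = 500L, target_sd = 0.25) {
  stopifnot(inherits(rt, "driftwatch_runtime"))
  role <- match.arg(role)
  if (!is.character(jid) || length(jid) != 1L || !nzchar(jid)) {
    stop("`jid` must be a non-empty string", call. = FALSE)
  }
  if (jid %in% names(rt$agents)) {
    stop("agent jid already registered: ", jid, call. = FALSE)
  }
  st <- new.env(parent = emptyenv())
  st$jid <- jid
  st$role <- role
  st$available <- TRUE
  if (role == "analyser") {
    st$identifier <- identifier
    st$detector <- if (is.null(detector)) adwin() else detector
    st$ctrl <- if (is.null(controller)) delta_controller() else controller
    st$detector$delta <- st$ctrl$delta
    st$scale <- scale
    st$target_sd <- target_sd
    st$cal_n <- if (identical(scale, "auto")) as.integer(calibration_samples)
                else 0L
    st$cal <- numeric(0)
    st$sigma_hat <- if (is.numeric(scale)) scale else NA_real_
    st$n_since_train <- 0L
    st$last_train_n <- 0L
    st$train_pending <- FALSE
  }
  rt$agents[[jid]] <- st
  log_event(rt, "register", jid = jid, role = role)
  invisible(list(jid = jid, role = role, available = TRUE))
}

get_agent <- function(rt, jid, role = NULL) {
  st <- rt$agents[[jid]]
  if (is.null(st)) stop("unknown agent jid: ", jid, call. = FALSE)
  if (!is.null(role) && st$role != role) {
    stop("agent ", jid, " has role ", st$role, ", expected ", role,
         call. = FALSE)
  }
  st
}

#' Toggle an agent's availability
#'
#' Availability gates delivery: Monitors send samples only to available
#' Analysers; unavailable subscribers receive nothing and the drop is
#' logged.
#'
#' @param rt A `driftwatch_runtime`.
#' @param jid Agent name.
#' @param available Logical.
#' @export
agent_set_available <- function(rt, jid, available) {
  st <- get_agent(rt, jid)
  st$available <- isTRUE(available)
  log_event(rt, "availability", jid = jid, available = st$available)
  invisible(NULL)
}

#' Subscribe an Analyser to a Monitor
#'
#' Establishes the reciprocal Monitor–Analyser link: the Analyser receives
#' the Monitor's samples, and the Monitor tracks the Analyser's
#' availability so it can withhold data when the Analyser is down.
#' Duplicate subscriptions are idempotent.
#'
#' @param rt A `driftwatch_runtime`.
#' @param analyser,monitor Registered agent names.
#' @export
subscribe <- function(rt, analyser, monitor) {
  stopifnot(inherits(rt, "driftwatch_runtime"))
  get_agent(rt, analyser, "analyser")
  get_agent(rt, monitor, "monitor")
  dup <- vapply(rt$subs, function(s) {
    s$subscriber == analyser && s$publisher == monitor
  }, logical(1))
  if (!any(dup)) {
    rt$subs[[length(rt$subs) + 1L]] <-
      list(subscriber = analyser, publisher = monitor, reciprocal = TRUE)
    log_event(rt, "subscribe", subscriber = analyser, publisher = monitor)
  }
  invisible(NULL)
}

#' Construct a sensor sample
#'
#' @param identifier Non-empty channel name (e.g. `"left_thigh"`).
#' @param value Measured value in microvolts.
#' @param timestamp_ms Non-negative milliseconds from stream start.
#' @param monitored_at Optional wall-clock POSIXct; filled in from the
#'   runtime clock on emission when omitted.
#' @return A `sensor_sample` list.
#' @export
sensor_sample <- function(identifier, value, timestamp_ms,
                          monitored_at = NULL) {
  if (!is.character(identifier) || !nzchar(identifier)) {
    stop("`identifier` must be a non-empty string", call. = FALSE)
  }
  if (!is.numeric(timestamp_ms) || timestamp_ms < 0) {
    stop("`timestamp_ms` must be >= 0", call. = FALSE)
  }
  structure(
    list(identifier = identifier, value = value,
         timestamp_ms = as.numeric(timestamp_ms),
         monitored_at = monitored_at),
    class = "sensor_sample"
  )
}

#' Emit a sample from a Monitor
#'
#' Delivers the sample to every subscribed, available Analyser; for
#' unavailable subscribers the sample is dropped and the drop logged (no
#' buffering, mirroring an availability-gated transport).
#'
#' @param rt A `driftwatch_runtime`.
#' @param monitor Monitor jid.
#' @param sample A [sensor_sample()].
#' @return Invisibly, a list of the prediction records produced (one per
#'   delivery).
#' @export
monitor_emit <- function(rt, monitor, sample) {
  get_agent(rt, monitor, "monitor")
  stopifnot(inherits(sample, "sensor_sample"))
  if (is.null(sample$monitored_at)) {
    sample$monitored_at <- as.POSIXct(
      rt$origin + sample$timestamp_ms / 1000, origin = "1970-01-01",
      tz = "UTC")
  }
  deliveries <- list()
  for (s in rt$subs) {
    if (s$publisher != monitor) next
    an <- rt$agents[[s$subscriber]]
    if (isTRUE(an$available)) {
      log_event(rt, "deliver", from = monitor, to = an$jid,
                t = sample$timestamp_ms, level = "debug")
      rec <- analyser_handle(rt, an$jid, sample)
      if (!is.null(rec)) deliveries[[length(deliveries) + 1L]] <- rec
    } else {
      rt$drops <- rt$drops + 1L
      log_event(rt, "drop", from = monitor, to = an$jid,
                t = sample$timestamp_ms)
    }
  }
  invisible(deliveries)
}

# fast JSON for the {"sensor": v} payload; matches canonical_json() output
sensor_payload <- function(v) {
  num <- ifelse(v == round(v), sprintf("%.0f", v),
                vapply(v, function(x) format(x, digits = 15,
                                             scientific = FALSE),
                       character(1)))
  paste0("{\"sensor\":", num, "}")
}

# standardize a raw value vector for one analyser; NULL while calibrating
analyser_scale <- function(st, values) {
  if (identical(st$scale, "none")) return(values)
  values * (st$target_sd / st$sigma_hat)
}

#' Let an Analyser predict one sample and persist the verdict
#'
#' Runs the Analyser's ADWIN detector on the (standardized) sample value
#' and appends one prediction record to the Knowledge Base, stamped with
#' the monitoring time and the analysis time. During the calibration period
#' of `scale = "auto"` the sample contributes to the scale estimate and is
#' persisted with `predicted = FALSE`. A failed Knowledge Base write is
#' retried once before surfacing; a sample for a channel the Analyser is
#' not bound to is skipped with a warning and nothing is persisted.
#'
#' No training computation happens here: when enough samples have
#' accumulated a retraining task is queued for [runtime_run_tasks()].
#'
#' @param rt A `driftwatch_runtime`.
#' @param jid Analyser name.
#' @param sample A [sensor_sample()].
#' @return The prediction record (one-row tibble), or `NULL` if skipped.
#' @export
analyser_handle <- function(rt, jid, sample) {
  st <- get_agent(rt, jid, "analyser")
  stopifnot(inherits(sample, "sensor_sample"))
  if (sample$identifier != st$identifier) {
    warning("analyser ", jid, " is bound to channel ", st$identifier,
            ", skipping sample for ", sample$identifier, call. = FALSE)
    return(NULL)
  }
  if (!is.numeric(sample$value) || !is.finite(sample$value)) {
    stop("non-finite value on channel ", sample$identifier, " at t = ",
         sample$timestamp_ms, " ms", call. = FALSE)
  }
  if (is.null(sample$monitored_at)) {
    sample$monitored_at <- as.POSIXct(
      rt$origin + sample$timestamp_ms / 1000, origin = "1970-01-01",
      tz = "UTC")
  }
  rt$in_predict <- TRUE
  on.exit(rt$in_predict <- FALSE)

  calibrating <- length(st$cal) < st$cal_n
  if (calibrating) {
    st$cal <- c(st$cal, sample$value)
    if (length(st$cal) == st$cal_n) freeze_scale(st)
    predicted <- FALSE
  } else {
    z <- analyser_scale(st, sample$value)
    res <- adwin_update(st$detector, z)
    st$detector <- res$state
    predicted <- res$drift
  }
  rec <- prediction_record(
    jid = jid,
    data = list(sensor = sample$value),
    datetime_monitored = sample$monitored_at,
    datetime_analysed = as.POSIXct(as.numeric(sample$monitored_at) +
                                     rt$latency,
                                   origin = "1970-01-01", tz = "UTC"),
    identifier = sample$identifier,
    predicted = predicted
  )
  kb_insert_retry(rt, rec)
  st$n_since_train <- st$n_since_train + 1L
  maybe_queue_training(rt, st)
  log_event(rt, "predict", jid = jid, t = sample$timestamp_ms,
            predicted = predicted, level = "debug")
  rec
}

freeze_scale <- function(st) {
  s <- stats::sd(st$cal)
  if (!is.finite(s) || s <= 0) s <- 1
  st$sigma_hat <- s
  invisible(NULL)
}

kb_insert_retry <- function(rt, records) {
  tryCatch(
    kb_insert(rt$kb, records),
    error = function(e) {
      # one retry, then surface
      kb_insert(rt$kb, records)
    }
  )
  invisible(NULL)
}

maybe_queue_training <- function(rt, st) {
  if (!st$train_pending && st$n_since_train >= st$ctrl$chunk_size) {
    st$train_pending <- TRUE
    rt$tasks <- c(rt$tasks, st$jid)
  }
  invisible(NULL)
}

# Bulk ingestion path used by run_pipeline(): semantically one
# analyser_handle() per element, with the loop kept internal. Records are
# inserted chunk-aligned so queued retraining (which queries the KB) always
# sees the finished chunk, and the confidence visible to predictions changes
# only at chunk boundaries.
analyser_ingest <- function(rt, jid, values, timestamps_ms) {
  st <- get_agent(rt, jid, "analyser")
  stopifnot(length(values) == length(timestamps_ms))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values))[1L]
    stop("non-finite value on channel ", st$identifier, " at t = ",
         timestamps_ms[bad], " ms", call. = FALSE)
  }
  drift_ts <- numeric(0)
  pos <- 0L
  n <- length(values)
  while (pos < n) {
    calibrating <- length(st$cal) < st$cal_n
    take <- if (calibrating) {
      min(st$cal_n - length(st$cal), n - pos)
    } else {
      min(st$ctrl$chunk_size - st$n_since_train, n - pos)
    }
    i <- (pos + 1L):(pos + take)
    seg <- values[i]
    rt$in_predict <- TRUE
    if (calibrating) {
      st$cal <- c(st$cal, seg)
      if (length(st$cal) >= st$cal_n) freeze_scale(st)
      flags <- logical(take)
    } else {
      res <- adwin_stream(st$detector, analyser_scale(st, seg))
      st$detector <- res$state
      flags <- res$drift
    }
    rt$in_predict <- FALSE
    mon <- rt$origin + timestamps_ms[i] / 1000
    recs <- tibble::tibble(
      jid = jid,
      data = sensor_payload(seg),
      datetime_monitored = as.POSIXct(mon, origin = "1970-01-01",
                                      tz = "UTC"),
      datetime_analysed = as.POSIXct(mon + rt$latency,
                                     origin = "1970-01-01", tz = "UTC"),
      identifier = st$identifier,
      predicted = flags
    )
    kb_insert_retry(rt, recs)
    drift_ts <- c(drift_ts, timestamps_ms[i][flags])
    if (!calibrating) {
      st$n_since_train <- st$n_since_train + take
      maybe_queue_training(rt, st)
    }
    runtime_run_tasks(rt)
    pos <- pos + take
  }
  list(n = n, drift_timestamps_ms = drift_ts)
}

#' Retrain an Analyser's confidence from the Knowledge Base
#'
#' The retraining task of the Analyser: it queries the Knowledge Base for
#' the records this Analyser has produced, derives the cumulative drift
#' rate from the persisted verdicts, applies one [step_delta()] and
#' publishes the new confidence to the detector. It is a no-op unless at
#' least `chunk_size` new records have accumulated since the last training
#' step. Training never runs inside the prediction path: predictions queue
#' this task and [runtime_run_tasks()] executes it between predictions.
#'
#' @param rt A `driftwatch_runtime`.
#' @param jid Analyser name.
#' @return Invisibly, the (possibly unchanged) confidence delta.
#' @export
analyser_retrain <- function(rt, jid) {
  st <- get_agent(rt, jid, "analyser")
  if (isTRUE(rt$in_predict)) {
    # contract violation: training computation inside the prediction path
    rt$train_in_predict <- rt$train_in_predict + 1L
  }
  recs <- kb_query_training(rt$kb, st$identifier, limit = Inf)
  n <- nrow(recs)
  if (n - st$last_train_n < st$ctrl$chunk_size) {
    return(invisible(st$ctrl$delta))
  }
  ctrl <- st$ctrl
  ctrl$samples_analysed <- n
  ctrl$drifts_accumulated <- sum(recs$predicted)
  rate <- drift_rate(ctrl)
  ctrl <- step_delta(ctrl, rate)
  st$ctrl <- ctrl
  st$detector$delta <- ctrl$delta
  st$last_train_n <- n
  st$n_since_train <- 0L
  st$train_pending <- FALSE
  log_event(rt, "retrain", jid = jid, rate = rate, delta = ctrl$delta)
  invisible(ctrl$delta)
}

#' Run queued asynchronous tasks
#'
#' Executes pending Analyser retraining tasks. Call between predictions (a
#' driver loop typically drains after each sample or batch); the
#' prediction path itself never executes training work.
#'
#' @param rt A `driftwatch_runtime`.
#' @return Invisibly, the number of tasks executed.
#' @export
runtime_run_tasks <- function(rt) {
  stopifnot(inherits(rt, "driftwatch_runtime"))
  done <- 0L
  while (length(rt$tasks)) {
    jid <- rt$tasks[[1L]]
    rt$tasks <- rt$tasks[-1L]
    analyser_retrain(rt, jid)
    done <- done + 1L
  }
  invisible(done)
}

#' @export
print.driftwatch_runtime <- function(x, ...) {
  roles <- vapply(x$agents, function(a) a$role, character(1))
  cat("<driftwatch runtime>\n")
  for (r in c("monitor", "analyser", "planner", "executor")) {
    cat("  ", r, "s: ", sum(roles == r), "\n", sep = "")
  }
  cat("  KB records:", kb_count(x$kb), "\n")
  invisible(x)
}
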