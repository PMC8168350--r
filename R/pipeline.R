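#' Configuration of the health-monitor pipeline
#'
#' Bundles every tunable of the end-to-end pipeline: the channel montage,
#' the confidence-regulation parameters, the Planner voting rule, the
#' Analyser standardization, and the Knowledge Base / sink locations.
#'
#' @param channels Character vector of channel (muscle) names, by input
#'   column order.
#' @param delta_start,delta_lower,delta_upper Confidence start value and
#'   decade boundaries (see [delta_controller()]).
#' @param chunk_size Samples per training step (2000 = 2 s at 1 kHz).
#' @param min_drifts,max_drifts,window_ms Planner voting rule (see
#'   [planner_rule()]).
#' @param scale,calibration_samples,target_sd Analyser input
#'   standardization (see [agent_register()]).
#' @param origin Stream epoch used to stamp samples.
#' @param kb_backend,kb_path Knowledge Base backend and (for `"file"`) its
#'   path.
#' @param sink Default alerts CSV path (`NULL` keeps alerts in memory).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(channels = default_channel_names(8L),
                            delta_start = 1.0, delta_lower = 1e-9,
                            delta_upper = 1.0, chunk_size = 2000L,
                            min_drifts = 2L, max_drifts = 8L,
                            window_ms = 1000,
                            scale = "auto", calibration_samples = 500L,
                            target_sd = 0.25,
                            origin = "2020-01-01 00:00:00",
                            kb_backend = c("memory", "file"),
                            kb_path = NULL, sink = NULL) {
  kb_backend <- match.arg(kb_backend)
  stopifnot(is.character(channels), length(channels) >= 1,
            !anyDuplicated(channels))
  structure(
    list(channels = channels,
         delta_start = delta_start, delta_lower = delta_lower,
         delta_upper = delta_upper, chunk_size = as.integer(chunk_size),
         min_drifts = as.integer(min_drifts),
         max_drifts = as.integer(max_drifts),
         window_ms = as.numeric(window_ms),
         scale = scale,
         calibration_samples = as.integer(calibration_samples),
         target_sd = as.numeric(target_sd),
         origin = as.POSIXct(origin, tz = "UTC"),
         kb_backend = kb_backend, kb_path = kb_path, sink = sink),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys: `channels` (list), `delta` (`start`, `lower`, `upper`,
#' `chunk_size`), `planner` (`min_drifts`, `max_drifts`, `window_ms`),
#' `analyser` (`scale`, `calibration_samples`, `target_sd`), `kb`
#' (`backend`, `path`), `sink`, `origin`. Missing keys fall back to the
#' [pipeline_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  arg <- function(value, default) if (is.null(value)) default else value
  d <- y$delta
  p <- y$planner
  a <- y$analyser
  k <- y$kb
  pipeline_config(
    channels = arg(unlist(y$channels), default_channel_names(8L)),
    delta_start = arg(d$start, 1.0),
    delta_lower = arg(d$lower, 1e-9),
    delta_upper = arg(d$upper, 1.0),
    chunk_size = arg(d$chunk_size, 2000L),
    min_drifts = arg(p$min_drifts, 2L),
    max_drifts = arg(p$max_drifts, 8L),
    window_ms = arg(p$window_ms, 1000),
    scale = arg(a$scale, "auto"),
    calibration_samples = arg(a$calibration_samples, 500L),
    target_sd = arg(a$target_sd, 0.25),
    origin = arg(y$origin, "2020-01-01 00:00:00"),
    kb_backend = arg(k$backend, "memory"),
    kb_path = k$path,
    sink = y$sink
  )
}

#' Run a recording through the full detection pipeline
#'
#' The end-to-end case study: every input row is fanned out as one sample
#' per channel to that channel's Monitor/Analyser pair; each Analyser runs
#' its ADWIN detector (with online confidence regulation retrained
#' asynchronously every `chunk_size` samples) and persists every verdict
#' to the Knowledge Base; the Planner votes over tumbling
#' `window_ms`-windows; fired alerts go through the Executor to the CSV
#' sink. Reruns of the same input and configuration are byte-identical.
#'
#' @param input Path to a headerless delimited recording (one row per ms,
#'   one column per channel), or an `emg_stream`/data frame/matrix.
#' @param config A [pipeline_config()].
#' @param output Alerts CSV path; defaults to `config$sink` (`NULL` keeps
#'   alerts in memory only).
#' @param quiet Suppress the printed run summary.
#' @return A `drift_run` object: alerts tibble, per-channel summary,
#'   totals, the populated Knowledge Base and runtime counters. Use
#'   [tidy()] for the alerts, [glance()] for the one-row summary.
#' @export
run_pipeline <- function(input, config = pipeline_config(), output = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  channels <- config$channels
  nch <- length(channels)
  if (is.character(input)) {
    data <- emg_read_csv(input, n_channels = nch, channel_names = channels)
  } else {
    data <- tibble::as_tibble(as.data.frame(input))
    data$time_ms <- NULL
    if (ncol(data) != nch) {
      stop("input has ", ncol(data), " channels, config expects ", nch,
           call. = FALSE)
    }
    names(data) <- channels
  }
  skipped <- attr(data, "skipped")
  if (is.null(skipped)) {
    skipped <- tibble::tibble(line = integer(0), reason = character(0))
  }
  n <- nrow(data)
  ts_ms <- seq_len(n) - 1

  kb <- if (config$kb_backend == "file") {
    kb_connect("file", config$kb_path)
  } else {
    kb_connect("memory")
  }
  rt <- runtime(kb, origin = config$origin)
  raw <- vector("list", nch)
  names(raw) <- channels
  for (ch in channels) {
    agent_register(rt, paste0("monitor_", ch), "monitor")
    agent_register(rt, paste0("analyser_", ch), "analyser",
                   identifier = ch,
                   detector = adwin(config$delta_start),
                   controller = delta_controller(
                     start = config$delta_start, lower = config$delta_lower,
                     upper = config$delta_upper,
                     chunk_size = config$chunk_size),
                   scale = config$scale,
                   calibration_samples = config$calibration_samples,
                   target_sd = config$target_sd)
    subscribe(rt, paste0("analyser_", ch), paste0("monitor_", ch))
  }
  if (n > 0) {
    for (ch in channels) {
      raw[[ch]] <- analyser_ingest(rt, paste0("analyser_", ch),
                                   data[[ch]], ts_ms)
    }
  }
  runtime_run_tasks(rt)

  if (is.null(output)) output <- config$sink
  executor <- executor_csv(output)
  rule <- planner_rule(config$min_drifts, config$max_drifts,
                       config$window_ms)
  alerts <- planner_run(kb, rule, executor, origin = config$origin)

  channel_summary <- tibble::tibble(
    identifier = channels,
    samples = vapply(raw, function(r) if (is.null(r)) 0L else r$n,
                     integer(1)),
    raw_drifts = vapply(raw, function(r) {
      if (is.null(r)) 0L else length(r$drift_timestamps_ms)
    }, integer(1)),
    sigma_hat = vapply(channels, function(ch) {
      rt$agents[[paste0("analyser_", ch)]]$sigma_hat
    }, numeric(1)),
    final_delta = vapply(channels, function(ch) {
      rt$agents[[paste0("analyser_", ch)]]$ctrl$delta
    }, numeric(1))
  )
  drift_positions <- tibble::tibble(
    identifier = rep(channels,
                     times = vapply(raw, function(r) {
                       if (is.null(r)) 0L else
                         length(r$drift_timestamps_ms)
                     }, integer(1))),
    timestamp_ms = unlist(lapply(raw, function(r) {
      if (is.null(r)) numeric(0) else r$drift_timestamps_ms
    }), use.names = FALSE)
  )
  res <- structure(
    list(alerts = alerts,
         channel_summary = channel_summary,
         drift_positions = drift_positions,
         rows_read = n,
         rows_skipped = nrow(skipped),
         skipped = skipped,
         predictions = kb_count(kb),
         raw_drifts = sum(channel_summary$raw_drifts),
         kb = kb,
         runtime = runtime_stats(rt),
         log = runtime_log(rt),
         config = config,
         output = output),
    class = "drift_run"
  )
  log_event(rt, "summary", rows_read = n, rows_skipped = nrow(skipped),
            predictions = res$predictions, raw_drifts = res$raw_drifts,
            alerts = nrow(alerts))
  if (!quiet) print(res)
  invisible(res)
}

#' @export
print.drift_run <- function(x, ...) {
  cat("<drift run>\n")
  cat("  rows read:          ", x$rows_read,
      if (x$rows_skipped) paste0(" (", x$rows_skipped, " skipped)") else "",
      "\n", sep = "")
  cat("  predictions written:", x$predictions, "\n")
  cat("  raw drifts per channel:\n")
  for (i in seq_len(nrow(x$channel_summary))) {
    cat(sprintf("    %-16s %5d  (final delta %s)\n",
                x$channel_summary$identifier[i],
                x$channel_summary$raw_drifts[i],
                format(x$channel_summary$final_delta[i])))
  }
  cat("  alerts fired:        ", nrow(x$alerts), "\n", sep = "")
  if (nrow(x$alerts)) {
    for (i in seq_len(nrow(x$alerts))) {
      cat(sprintf("    [%g, %g) ms: %d channel(s): %s\n",
                  x$alerts$window_start_ms[i], x$alerts$window_end_ms[i],
                  x$alerts$n_drift[i], x$alerts$identifiers[i]))
    }
  }
  invisible(x)
}

#' Alerts of a pipeline run
#' @param x A `drift_run`.
#' @param ... Unused.
#' @return The alerts tibble (one row per fired alert).
#' @export
tidy.drift_run <- function(x, ...) {
  x$alerts
}

#' One-row summary of a pipeline run
#' @param x A `drift_run`.
#' @param ... Unused.
#' @return A one-row tibble: rows read/skipped, predictions persisted, raw
#'   per-channel drift detections, alerts fired, and the
#'   asynchronous-training contract counter (must be 0).
#' @export
glance.drift_run <- function(x, ...) {
  tibble::tibble(
    rows_read = x$rows_read,
    rows_skipped = x$rows_skipped,
    predictions = x$predictions,
    raw_drifts = x$raw_drifts,
    alerts = nrow(x$alerts),
    train_in_predict = x$runtime$train_in_predict
  )
}
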