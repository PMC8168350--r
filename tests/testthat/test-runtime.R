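new_runtime <- function(...) {
  runtime(kb_connect("memory"), ...)
}

register_pair <- function(rt, ch = "left_thigh", scale = "none",
                          delta = 0.002, chunk_size = 2000L) {
  agent_register(rt, paste0("m_", ch), "monitor")
  agent_register(rt, paste0("a_", ch), "analyser", identifier = ch,
                 detector = adwin(delta),
                 controller = delta_controller(start = delta,
                                               chunk_size = chunk_size),
                 scale = scale)
  subscribe(rt, paste0("a_", ch), paste0("m_", ch))
}

emit_value <- function(rt, ch, value, t_ms) {
  monitor_emit(rt, paste0("m_", ch),
               sensor_sample(ch, value, t_ms))
}

test_that("subscriptions are reciprocal, idempotent and validated", {
  rt <- new_runtime()
  agent_register(rt, "m1", "monitor")
  agent_register(rt, "a1", "analyser", identifier = "left_thigh")
  subscribe(rt, "a1", "m1")
  expect_length(rt$subs, 1L)
  expect_true(rt$subs[[1]]$reciprocal)
  subscribe(rt, "a1", "m1")              # duplicate: idempotent
  expect_length(rt$subs, 1L)
  expect_error(subscribe(rt, "a1", "nope"), "unknown agent")
  expect_error(subscribe(rt, "nope", "m1"), "unknown agent")
  expect_length(rt$subs, 1L)             # registry unchanged after errors
  expect_error(agent_register(rt, "m1", "monitor"), "already registered")
})

test_that("monitors deliver only to available analysers and log drops", {
  # enumerate availability patterns for up to 3 subscribers
  for (pattern in list(TRUE, FALSE, c(TRUE, TRUE), c(TRUE, FALSE),
                       c(FALSE, FALSE), c(TRUE, FALSE, TRUE))) {
    rt <- new_runtime()
    agent_register(rt, "m1", "monitor")
    for (i in seq_along(pattern)) {
      agent_register(rt, paste0("a", i), "analyser",
                     identifier = "left_thigh")
      subscribe(rt, paste0("a", i), "m1")
      agent_set_available(rt, paste0("a", i), pattern[i])
    }
    out <- monitor_emit(rt, "m1", sensor_sample("left_thigh", 1.0, 0))
    expect_length(out, sum(pattern))
    got_jids <- vapply(out, function(r) r$jid, character(1))
    want_jids <- if (any(pattern)) paste0("a", which(pattern))
                 else character(0)
    expect_identical(sort(got_jids), want_jids)
    expect_identical(rt$drops, sum(!pattern))
    expect_identical(kb_count(rt$kb), sum(pattern))
    if (any(!pattern)) {
      expect_true(any(grepl("\"event\":\"drop\"", runtime_log(rt))))
    }
  }
})

test_that("with every analyser unavailable the knowledge base stays empty", {
  rt <- new_runtime()
  register_pair(rt)
  agent_set_available(rt, "a_left_thigh", FALSE)
  for (t in 0:49) emit_value(rt, "left_thigh", rnorm(1), t)
  expect_identical(kb_count(rt$kb), 0L)
  expect_identical(rt$drops, 50L)
})

test_that("analyser predictions persist one record per delivered sample", {
  rt <- new_runtime()
  register_pair(rt)
  for (t in 0:9) emit_value(rt, "left_thigh", 0, t)
  recs <- kb_records(rt$kb)
  expect_identical(nrow(recs), 10L)       # count conservation
  expect_identical(unique(recs$jid), "a_left_thigh")
  expect_identical(unique(recs$identifier), "left_thigh")
  expect_false(any(recs$predicted))
  expect_identical(unique(recs$data[1]), "{\"sensor\":0}")
  expect_true(all(recs$datetime_analysed >= recs$datetime_monitored))

  # a stream with a detectable shift: verdicts match the detector oracle
  set.seed(31)
  x <- stream_mean_shift(300, 150, 8)
  orc <- oracle_adwin(x, 0.002)
  rt <- new_runtime()
  register_pair(rt)
  for (i in seq_along(x)) emit_value(rt, "left_thigh", x[i], i - 1)
  recs <- kb_records(rt$kb)
  expect_identical(which(recs$predicted), orc$positions)

  # non-finite sample: rejected naming channel and time, nothing persisted
  n_before <- kb_count(rt$kb)
  expect_error(emit_value(rt, "left_thigh", Inf, 1000),
               "left_thigh at t = 1000")
  expect_identical(kb_count(rt$kb), n_before)

  # sample for a channel the analyser is not bound to: skipped with warning
  expect_warning(
    analyser_handle(rt, "a_left_thigh",
                    sensor_sample("right_thigh", 1, 0)),
    "bound to channel"
  )
  expect_identical(kb_count(rt$kb), n_before)
})

test_that("retraining runs at chunk cadence and publishes delta between chunks", {
  set.seed(5)
  chunk <- 50L
  x <- c(rep(0, 25), rep(10, 25), rnorm(100, 0, 0.25))
  rt <- new_runtime()
  register_pair(rt, delta = 1.0, chunk_size = chunk)
  # reference trace: the standalone training loop on the same raw stream
  ref_ctrl <- delta_controller(chunk_size = chunk)
  ref_det <- adwin(ref_ctrl$delta)
  ref_deltas <- numeric(0)
  for (start in seq(1, length(x), by = chunk)) {
    out <- train_on_chunk(ref_ctrl, ref_det, x[start:(start + chunk - 1)])
    ref_ctrl <- out$ctrl; ref_det <- out$state
    ref_deltas <- c(ref_deltas, ref_ctrl$delta)
  }

  seen <- numeric(length(x))
  st <- rt$agents[["a_left_thigh"]]
  for (i in seq_along(x)) {
    seen[i] <- st$detector$delta        # delta visible to this prediction
    emit_value(rt, "left_thigh", x[i], i - 1)
    runtime_run_tasks(rt)
  }
  # delta changes only at chunk boundaries and follows the reference trace
  expect_identical(unique(seen[1:chunk]), 1.0)
  expect_identical(unique(seen[(chunk + 1):(2 * chunk)]), ref_deltas[1])
  expect_identical(unique(seen[(2 * chunk + 1):(3 * chunk)]), ref_deltas[2])
  expect_identical(st$ctrl$delta, ref_deltas[3])
  expect_identical(st$ctrl$samples_analysed, 150L)

  # before cadence is reached retraining is a no-op
  rt2 <- new_runtime()
  register_pair(rt2, chunk_size = 1000L)
  for (t in 0:9) emit_value(rt2, "left_thigh", 0, t)
  d0 <- rt2$agents[["a_left_thigh"]]$ctrl$delta
  analyser_retrain(rt2, "a_left_thigh")
  expect_identical(rt2$agents[["a_left_thigh"]]$ctrl$delta, d0)
})

test_that("training work never executes inside the prediction path", {
  set.seed(6)
  rt <- new_runtime()
  register_pair(rt, chunk_size = 40L)
  for (i in 1:200) {
    emit_value(rt, "left_thigh", rnorm(1, 0, 0.25), i - 1)
    runtime_run_tasks(rt)
  }
  stats <- runtime_stats(rt)
  expect_identical(stats$train_in_predict, 0L)
  expect_identical(stats$pending_tasks, 0L)
  # retraining did actually happen, asynchronously
  expect_true(any(grepl("\"event\":\"retrain\"", runtime_log(rt))))
})

test_that("polling returns each record exactly once via the cursor", {
  kb <- kb_connect("memory")
  t0 <- as.POSIXct("2020-07-21 14:00:00", tz = "UTC")
  mk <- function(i) prediction_record("a1", list(sensor = i), t0 + i,
                                      t0 + i, "left_thigh", FALSE)
  first <- planner_poll(kb)
  expect_identical(nrow(first), 0L)

  for (i in 1:3) kb_insert(kb, mk(i))
  got <- planner_poll(kb, since = 0)
  expect_identical(nrow(got), 3L)
  cursor <- attr(got, "cursor")

  for (i in 4:5) kb_insert(kb, mk(i))
  more <- planner_poll(kb, since = cursor)
  expect_identical(more$data, sprintf("{\"sensor\":%d}", 4:5))
  expect_identical(nrow(planner_poll(kb, since = attr(more, "cursor"))), 0L)
})

test_that("executors hold alerts while the sink is down and recover in order", {
  mk_alert <- function(i) {
    structure(list(window_start_ms = i * 1000, window_end_ms = (i + 1) * 1000,
                   n_drift = 2L, identifiers = c("a", "b"),
                   decided_at = as.POSIXct("2020-01-01", tz = "UTC") + i),
              class = "drift_alert")
  }
  ex <- executor_csv()
  expect_identical(executor_deliver(ex, mk_alert(1)), "delivered")

  sink_state <- new.env()
  sink_state$alive <- TRUE
  ex <- executor_csv(path = withr::local_tempfile(fileext = ".csv"),
                     alive = function() sink_state$alive)
  statuses <- character(5)
  for (i in 1:5) {
    if (i == 3) sink_state$alive <- FALSE
    if (i == 5) sink_state$alive <- TRUE
    statuses[i] <- executor_deliver(ex, mk_alert(i))
  }
  expect_identical(statuses, c("delivered", "delivered", "held", "held",
                               "delivered"))
  done <- executor_alerts(ex)
  expect_identical(done$window_start_ms, (1:5) * 1000)  # original order
  on_disk <- readLines(ex$path)
  expect_length(on_disk, 6L)  # header + 5 alerts
  expect_match(on_disk[2], "^1000,2000,2,a;b,")
})
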