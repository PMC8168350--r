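# every KB behaviour is checked on both backends through the same interface
kb_backends <- function() {
  list(
    memory = kb_connect("memory"),
    file = kb_connect("file", withr::local_tempfile(fileext = ".tsv",
                                                    .local_envir = parent.frame()))
  )
}

example_record <- function() {
  prediction_record(
    jid = "Custom drift analyser",
    data = list(sensor = 429),
    datetime_monitored = "2020-07-21 14:36:00",
    datetime_analysed = "2020-07-21 14:37:00",
    identifier = "left_thigh",
    predicted = FALSE
  )
}

test_that("the schema example row inserts and reads back field-identical", {
  for (kb in kb_backends()) {
    kb_insert(kb, example_record())
    got <- kb_records(kb)
    expect_identical(nrow(got), 1L)
    expect_identical(got$jid, "Custom drift analyser")
    expect_identical(got$data, "{\"sensor\":429}")
    expect_identical(format(got$datetime_monitored, "%Y-%m-%d %H:%M:%S",
                            tz = "UTC"), "2020-07-21 14:36:00")
    expect_identical(format(got$datetime_analysed, "%Y-%m-%d %H:%M:%S",
                            tz = "UTC"), "2020-07-21 14:37:00")
    expect_identical(got$identifier, "left_thigh")
    expect_identical(got$predicted, FALSE)
  }
})

test_that("invariant-violating records are rejected before any write", {
  expect_error(
    prediction_record("a", list(s = 1), "2020-07-21 14:37:00",
                      "2020-07-21 14:36:00", "left_thigh", FALSE),
    "precedes"
  )
  expect_error(
    prediction_record("a", list(s = 1), "2020-07-21 14:36:00",
                      "2020-07-21 14:37:00", "", FALSE),
    "identifier"
  )
  expect_error(
    prediction_record("a", list(s = 1), "2020-07-21 14:36:00",
                      "2020-07-21 14:37:00", "left_thigh", NA),
    "predicted"
  )
  expect_error(canonical_json("{not json"), "valid JSON")

  for (kb in kb_backends()) {
    bad <- example_record()
    bad$datetime_analysed <- bad$datetime_monitored - 60
    expect_error(kb_insert(kb, bad), "precedes")
    expect_identical(kb_count(kb), 0L)
  }
})

test_that("inserts are conserved and timestamps keep millisecond precision", {
  t0 <- as.POSIXct("2021-03-01 08:00:00", tz = "UTC")
  recs <- tibble::tibble(
    jid = "a1",
    data = sprintf("{\"sensor\":%d}", 1:1000),
    datetime_monitored = t0 + (1:1000) / 1000,
    datetime_analysed = t0 + (1:1000) / 1000 + 0.001,
    identifier = "left_thigh",
    predicted = rep(c(TRUE, FALSE), 500)
  )
  for (kb in kb_backends()) {
    kb_insert(kb, recs)
    expect_identical(kb_count(kb), 1000L)
    got <- kb_records(kb)
    expect_equal(as.numeric(got$datetime_monitored),
                 as.numeric(recs$datetime_monitored), tolerance = 1e-6)
    expect_identical(got$data, recs$data)
    expect_identical(got$predicted, recs$predicted)
  }
})

test_that("window queries match a brute-force filter of the record list", {
  set.seed(21)
  t0 <- as.POSIXct("2020-07-21 14:00:00", tz = "UTC")
  n <- 20
  recs <- tibble::tibble(
    jid = sample(c("a1", "a2"), n, replace = TRUE),
    data = sprintf("{\"sensor\":%d}", sample(100:999, n)),
    datetime_monitored = t0 + round(runif(n, 0, 60), 3),
    identifier = sample(c("left_thigh", "right_thigh"), n, replace = TRUE),
    predicted = sample(c(TRUE, FALSE), n, replace = TRUE)
  )
  recs$datetime_analysed <- recs$datetime_monitored + 0.5

  for (kb in kb_backends()) {
    expect_identical(nrow(kb_query_window(kb, t0, t0 + 60)), 0L)
    kb_insert(kb, recs)
    for (win in list(c(0, 60), c(10, 30), c(25, 25.5))) {
      since <- t0 + win[1]; until <- t0 + win[2]
      got <- kb_query_window(kb, since, until)
      ana <- as.numeric(recs$datetime_analysed)
      want <- recs[ana > as.numeric(since) & ana <= as.numeric(until), ]
      want <- want[order(as.numeric(want$datetime_analysed), want$jid), ]
      expect_equal(as.numeric(got$datetime_analysed),
                   as.numeric(want$datetime_analysed), tolerance = 1e-6)
      expect_identical(got$jid, want$jid)
      expect_identical(got$data, want$data)

      only <- kb_query_window(kb, since, until, predicted_only = TRUE)
      expect_identical(only$data, want$data[want$predicted])
    }
    expect_error(kb_query_window(kb, t0 + 10, t0), "since")
  }
})

test_that("training queries return the newest records per channel, oldest first", {
  t0 <- as.POSIXct("2020-07-21 14:00:00", tz = "UTC")
  mk <- function(i, ident) {
    prediction_record("a1", list(sensor = i), t0 + i, t0 + i + 1,
                      ident, i %% 2 == 0)
  }
  for (kb in kb_backends()) {
    # interleave two channels
    for (i in 1:10) {
      kb_insert(kb, mk(i, if (i %% 2) "left_thigh" else "right_thigh"))
    }
    left <- kb_query_training(kb, "left_thigh", limit = Inf)
    expect_identical(left$data, sprintf("{\"sensor\":%d}", c(1, 3, 5, 7, 9)))
    top2 <- kb_query_training(kb, "left_thigh", limit = 2)
    expect_identical(top2$data, sprintf("{\"sensor\":%d}", c(7, 9)))
    all_of_them <- kb_query_training(kb, "right_thigh", limit = 100)
    expect_identical(nrow(all_of_them), 5L)
    expect_identical(nrow(kb_query_training(kb, "no_such_channel")), 0L)
  }
})

test_that("canonical JSON is key-sorted and byte-stable across round trips", {
  a <- canonical_json(list(b = 1, a = list(z = 2, y = "x")))
  b <- canonical_json("{\"a\": {\"y\": \"x\", \"z\": 2}, \"b\": 1}")
  expect_identical(a, b)
  expect_identical(canonical_json(a), a)
  expect_identical(canonical_json(list(sensor = 429)), "{\"sensor\":429}")
})
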