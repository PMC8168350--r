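test_that("a single element admits no split and constant streams never drift", {
  det <- adwin(0.002)
  res <- adwin_update(det, 0.0)
  expect_false(res$drift)
  expect_identical(res$state$elements, 0.0)
  expect_identical(res$state$total_seen, 1L)

  res <- adwin_stream(adwin(0.002), rep(0, 1000))
  expect_false(any(res$drift))
  expect_identical(res$state$drifts_detected, 0L)
  expect_length(res$state$elements, 1000L)

  # all subwindow means equal: no cut at any delta
  expect_false(adwin_find_cut(
    structure(list(elements = c(5, 5, 5, 5), delta = 0.9),
              class = "adwin"))$cut_found)
})

test_that("epsilon_cut matches its closed form and the expected monotonicities", {
  expect_equal(epsilon_cut(100, 100, 200, 0.002),
               sqrt(0.01 * log(4 * 200 / 0.002)), tolerance = 1e-12)
  expect_equal(epsilon_cut(100, 100, 200, 0.002), 0.3592, tolerance = 1e-3)

  # growing both subwindows shrinks the threshold
  eps <- vapply(c(10, 20, 40), function(m) epsilon_cut(m, m, 2 * m, 0.002),
                numeric(1))
  expect_true(all(diff(eps) < 0))

  # higher confidence delta = more sensitive = smaller threshold
  expect_lt(epsilon_cut(50, 50, 100, 1.0), epsilon_cut(50, 50, 100, 0.001))

  expect_gt(epsilon_cut(1, 1, 2, 1.0), 0)
  expect_error(epsilon_cut(0, 5, 5, 0.1), "n0")
  expect_error(epsilon_cut(5, 5, 11, 0.1), "n0 \\+ n1")
  expect_error(epsilon_cut(5, 5, 10, 0), "delta")
  expect_error(epsilon_cut(5, 5, 10, 1.5), "delta")
  expect_error(adwin(0), "delta")
  expect_error(adwin(2), "delta")
})

test_that("find_cut returns the oldest qualifying split with a consistent threshold", {
  # two-element window: outcome decided by direct evaluation of the bound
  st <- structure(list(elements = c(0, 10), delta = 0.5), class = "adwin")
  cut <- adwin_find_cut(st)
  expect_true(cut$cut_found)  # |0 - 10| = 10 >= sqrt(ln 16) ~ 1.665
  expect_identical(cut$split_index, 1L)
  expect_equal(cut$epsilon, epsilon_cut(1, 1, 2, 0.5), tolerance = 1e-12)
  expect_gte(abs(cut$mean_w0 - cut$mean_w1), cut$epsilon)

  # a large level shift: many splits qualify; the oldest one is reported
  w <- c(rep(0, 100), rep(10, 100))
  st <- structure(list(elements = w, delta = 0.002), class = "adwin")
  cut <- adwin_find_cut(st)
  expect_true(cut$cut_found)
  expect_gte(abs(cut$mean_w0 - cut$mean_w1), cut$epsilon)
  # verify "oldest": no earlier split reaches its own threshold
  k <- cut$split_index
  if (k > 1L) {
    earlier <- vapply(1:(k - 1L), function(j) {
      abs(mean(w[1:j]) - mean(w[(j + 1):200])) >=
        epsilon_cut(j, 200 - j, 200, 0.002)
    }, logical(1))
    expect_false(any(earlier))
  }
  # hand arithmetic: split 1 itself qualifies here (5.025 >= 2.55)
  expect_identical(k, 1L)
})

test_that("a mean shift is detected promptly and the stale regime is purged", {
  set.seed(4711)
  x <- stream_mean_shift(1000, at = 500, size = 10)
  res <- run_adwin(x, 0.002)
  expect_gt(length(res$positions), 0)
  first <- res$positions[res$positions > 500][1]
  expect_false(is.na(first))
  expect_lte(first, 600)

  # the retained window right after the first post-shift drift matches the
  # oracle's, i.e. only elements the exhaustive search keeps survive
  orc <- oracle_adwin(x, 0.002)
  expect_identical(res$positions, orc$positions)
  i <- which(orc$positions == first)
  det <- adwin(0.002)
  upd <- adwin_stream(det, x[1:first])
  expect_identical(upd$state$elements, orc$windows_after[[i]])
})

test_that("streaming updates agree with the exhaustive-split oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    kind <- seed %% 3
    x <- if (kind == 0) stream_stationary(300)
         else if (kind == 1) stream_mean_shift(300, 150, 5)
         else stream_var_shift(300, 150, 16)
    for (delta in c(0.002, 0.05)) {
      res <- run_adwin(x, delta)
      orc <- oracle_adwin(x, delta)
      expect_identical(res$positions, orc$positions)
      expect_identical(res$state$elements, orc$window)
    }
  }
})

test_that("post-drift purge, counters and determinism hold along a stream", {
  set.seed(99)
  x <- stream_mean_shift(600, 300, 8)
  det <- adwin(0.002)
  positions <- integer(0)
  for (i in seq_along(x)) {
    res <- adwin_update(det, x[i])
    det <- res$state
    if (res$drift) {
      positions <- c(positions, i)
      # the retained window is exactly the newest elements of the stream
      nk <- length(det$elements)
      expect_identical(det$elements, x[(i - nk + 1):i])
    }
    expect_identical(det$total_seen, i)
    expect_lte(det$drifts_detected, det$total_seen)
  }
  # bit-for-bit repeatability
  rerun <- run_adwin(x, 0.002)
  expect_identical(rerun$positions, positions)
})

test_that("detection delay shrinks as the shift grows", {
  delays <- sapply(c(2, 5, 10), function(s) {
    mean(sapply(1:50, function(seed) {
      set.seed(1000 + seed)
      x <- stream_mean_shift(400, at = 200, size = s, sigma = 0.5)
      res <- run_adwin(x, 0.002)
      hit <- res$positions[res$positions > 200]
      if (length(hit)) hit[1] - 200 else 200
    }))
  })
  expect_true(all(diff(delays) <= 0))
})

test_that("non-finite values are rejected with a diagnostic", {
  det <- adwin(0.002)
  expect_error(adwin_update(det, NA_real_), "finite")
  expect_error(adwin_update(det, Inf), "finite")
  expect_error(adwin_stream(det, c(1, 2, NaN, 4)), "position 3")
})
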