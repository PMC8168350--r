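# Brute-force ADWIN oracle, written independently of the package internals:
# it keeps an explicit window, re-scans every split with scalar running sums
# on every step, truncates at the oldest qualifying split and repeats until
# no split qualifies. Used to pin down the expected drift positions and
# retained windows of the streaming implementation.
oracle_adwin <- function(values, delta) {
  w <- numeric(0)
  positions <- integer(0)
  windows_after <- list()
  for (i in seq_along(values)) {
    w <- c(w, values[i])
    fired <- FALSE
    repeat {
      n <- length(w)
      if (n < 2L) break
      total <- 0
      for (x in w) total <- total + x
      cut_at <- 0L
      s0 <- 0
      for (k in 1:(n - 1L)) {
        s0 <- s0 + w[k]
        mu0 <- s0 / k
        mu1 <- (total - s0) / (n - k)
        mh <- 1 / (1 / k + 1 / (n - k))
        eps <- sqrt((1 / (2 * mh)) * log(4 * n / delta))
        if (abs(mu0 - mu1) >= eps) {
          cut_at <- k
          break
        }
      }
      if (cut_at == 0L) break
      w <- w[-(1:cut_at)]
      fired <- TRUE
    }
    if (fired) {
      positions <- c(positions, i)
      windows_after[[length(positions)]] <- w
    }
  }
  list(positions = positions, window = w, windows_after = windows_after)
}

# stream builders used across suites
stream_stationary <- function(n, sigma = 1) rnorm(n, 0, sigma)

stream_mean_shift <- function(n, at, size, sigma = 1) {
  c(rnorm(at, 0, sigma), rnorm(n - at, size * sigma, sigma))
}

stream_var_shift <- function(n, at, mult, sigma = 1) {
  c(rnorm(at, 0, sigma), rnorm(n - at, 0, sigma * sqrt(mult)))
}

run_adwin <- function(values, delta) {
  adwin_stream(adwin(delta), values)
}
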