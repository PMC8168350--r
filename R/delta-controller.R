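#' Create an adaptive-delta controller
#'
#' Regulates the ADWIN confidence `delta` for one stream from the observed
#' drift rate. Whenever the cumulative drift rate (drifts detected over
#' samples analysed) increases relative to the rate recorded at the last
#' change, `delta` is divided by 10; whenever it decreases, `delta` is
#' multiplied by 10 — always staying inside `[lower, upper]` and moving only
#' in whole decades. `last_rate` is updated only when `delta` actually
#' changes, which keeps small rate fluctuations from flapping the
#' confidence.
#'
#' @param start Initial confidence; defaults to the most sensitive value 1.0.
#' @param lower,upper Decade boundaries for `delta`.
#' @param chunk_size Number of samples per training step; 2000 corresponds
#'   to 2 seconds of a 1 kHz stream.
#' @return An object of class `delta_controller`.
#' @seealso [step_delta()], [drift_rate()], [train_on_chunk()]
#' @export
delta_controller <- function(start = 1.0, lower = 1e-9, upper = 1.0,
                             chunk_size = 2000L) {
  stopifnot(
    is.numeric(lower), is.numeric(upper), length(lower) == 1L,
    length(upper) == 1L, lower > 0, upper <= 1, lower <= upper,
    is.numeric(start), length(start) == 1L,
    is.numeric(chunk_size), length(chunk_size) == 1L, chunk_size >= 1
  )
  if (start < lower || start > upper) {
    stop("`start` must lie within [lower, upper]", call. = FALSE)
  }
  structure(
    list(
      delta = start,
      start = start,
      exponent = 0L,    # delta == start * 10^-exponent, exact by re-derivation
      lower = lower,
      upper = upper,
      last_rate = 0,
      drifts_accumulated = 0L,
      samples_analysed = 0L,
      chunk_size = as.integer(chunk_size)
    ),
    class = "delta_controller"
  )
}

#' Cumulative drift rate of a controller
#'
#' The accumulated number of drift detections over the number of samples
#' analysed since the controller was created. Defined as 0 before any sample
#' has been analysed (cold start).
#'
#' @param ctrl A `delta_controller`.
#' @return A number in \[0, 1\].
#' @export
drift_rate <- function(ctrl) {
  stopifnot(inherits(ctrl, "delta_controller"))
  if (ctrl$samples_analysed == 0L) return(0)
  ctrl$drifts_accumulated / ctrl$samples_analysed
}

#' Apply one confidence-regulation step
#'
#' Compares `rate` with the rate recorded at the last confidence change and
#' moves `delta` one decade down (rate increased), one decade up (rate
#' decreased), or not at all (equal rate, or a boundary blocks the move).
#' When a boundary blocks the move, `last_rate` is left untouched.
#'
#' @param ctrl A `delta_controller`.
#' @param rate Observed drift rate in \[0, 1\].
#' @return The updated controller.
#' @examples
#' ctrl <- delta_controller()
#' ctrl <- step_delta(ctrl, 0.05)   # rate rose from 0: delta 1.0 -> 0.1
#' ctrl$delta
#' @export
step_delta <- function(ctrl, rate) {
  stopifnot(inherits(ctrl, "delta_controller"))
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) ||
      rate < 0 || rate > 1) {
    stop("`rate` must be a single number in [0, 1]", call. = FALSE)
  }
  # exponent arithmetic keeps decades exact over long call sequences
  down <- ctrl$start * 10^(-(ctrl$exponent + 1L))
  up <- ctrl$start * 10^(-(ctrl$exponent - 1L))
  if (rate > ctrl$last_rate && down >= ctrl$lower * (1 - 1e-9)) {
    ctrl$exponent <- ctrl$exponent + 1L
    ctrl$delta <- down
    ctrl$last_rate <- rate
  } else if (rate < ctrl$last_rate && up <= ctrl$upper * (1 + 1e-9)) {
    ctrl$exponent <- ctrl$exponent - 1L
    ctrl$delta <- up
    ctrl$last_rate <- rate
  }
  ctrl
}

#' Train a detector/controller pair on one chunk of raw values
#'
#' Feeds every chunk element through the detector at the controller's
#' current confidence, accumulates the drift and sample counters, then
#' applies exactly one [step_delta()] using the cumulative [drift_rate()]
#' and publishes the (possibly changed) confidence to the detector for
#' subsequent data. An empty chunk is a no-op.
#'
#' @param ctrl A `delta_controller`.
#' @param state An `adwin` detector.
#' @param chunk Numeric vector of raw stream values.
#' @return A list with the updated `ctrl` and `state`.
#' @export
train_on_chunk <- function(ctrl, state, chunk) {
  stopifnot(inherits(ctrl, "delta_controller"), inherits(state, "adwin"))
  if (!length(chunk)) return(list(ctrl = ctrl, state = state))
  state$delta <- ctrl$delta
  res <- adwin_stream(state, chunk)
  state <- res$state
  ctrl$samples_analysed <- ctrl$samples_analysed + length(chunk)
  ctrl$drifts_accumulated <- ctrl$drifts_accumulated + sum(res$drift)
  ctrl <- step_delta(ctrl, drift_rate(ctrl))
  state$delta <- ctrl$delta
  list(ctrl = ctrl, state = state)
}

#' @export
print.delta_controller <- function(x, ...) {
  cat("<delta controller>\n")
  cat("  delta:     ", format(x$delta), " in [", format(x$lower), ", ",
      format(x$upper), "]\n", sep = "")
  cat("  last rate: ", format(x$last_rate), "\n")
  cat("  drifts/samples: ", x$drifts_accumulated, "/", x$samples_analysed,
      "\n", sep = "")
  invisible(x)
}
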