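#' Create an ADWIN change detector
#'
#' ADWIN (ADaptive WINdowing) keeps a variable-length window of the most
#' recent stream values and flags a concept drift whenever the window can be
#' split into an older part `W0` and a newer part `W1` whose means differ by
#' more than a confidence-controlled threshold (see [epsilon_cut()]). On a
#' drift the stale older part is discarded, so the window always represents
#' the current regime.
#'
#' The detector stores every element explicitly and searches every split on
#' every update. This exact formulation is O(n) per update via prefix sums;
#' it trades speed for verifiability against a brute-force oracle, which is
#' the right trade at the scale of per-channel physiological streams.
#'
#' @param delta Confidence parameter in (0, 1]. Higher values make the
#'   detector more sensitive (it flags smaller deviations); `delta = 1` is
#'   the most sensitive admissible setting.
#' @return An object of class `adwin`: a list with fields `elements`
#'   (current window, newest last), `delta`, `total_seen` and
#'   `drifts_detected`.
#' @seealso [adwin_update()], [adwin_stream()], [adwin_find_cut()]
#' @examples
#' det <- adwin(delta = 0.002)
#' res <- adwin_update(det, 0.5)
#' res$drift
#' @export
adwin <- function(delta = 0.002) {
  check_delta(delta)
  structure(
    list(
      elements = numeric(0),
      delta = delta,
      total_seen = 0L,
      drifts_detected = 0L
    ),
    class = "adwin"
  )
}

check_delta <- function(delta) {
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta <= 0 || delta > 1) {
    stop("`delta` must be a single number in (0, 1], got ",
         deparse(substitute(delta)), " = ", format(delta), call. = FALSE)
  }
  invisible(delta)
}

#' Split threshold for the ADWIN mean comparison
#'
#' The cut threshold is a Hoeffding-style bound with the confidence shared
#' (Bonferroni) across the `n` candidate splits of the window:
#' \deqn{\epsilon = \sqrt{\frac{1}{2m} \ln\frac{4n}{\delta}}, \qquad
#'       m = \frac{1}{1/n_0 + 1/n_1}}
#' where `m` is the harmonic mean of the two subwindow sizes. The bound is
#' calibrated for values of bounded range 1 (standard deviation at most 1/2);
#' inputs on other scales must be standardized before being fed to the
#' detector (the pipeline Analysers do this, see [run_pipeline()]).
#'
#' @param n0,n1 Sizes of the older and newer subwindow (each at least 1).
#' @param n Total window size, must equal `n0 + n1`.
#' @param delta Confidence in (0, 1].
#' @return The positive threshold on `|mean(W0) - mean(W1)|`.
#' @examples
#' epsilon_cut(100, 100, 200, 0.002)
#' @export
epsilon_cut <- function(n0, n1, n, delta) {
  if (!is.numeric(n0) || !is.numeric(n1) || any(n0 < 1) || any(n1 < 1)) {
    stop("subwindow sizes `n0` and `n1` must be counts >= 1", call. = FALSE)
  }
  if (any(n != n0 + n1)) {
    stop("`n` must equal `n0 + n1`", call. = FALSE)
  }
  check_delta(delta)
  m <- 1 / (1 / n0 + 1 / n1)
  sqrt(log(4 * n / delta) / (2 * m))
}

# Vectorised search over all splits of window `w`; returns the oldest
# (smallest-index) qualifying split or 0L when none qualifies.
find_cut_index <- function(w, delta) {
  n <- length(w)
  if (n < 2L) return(0L)
  cs <- cumsum(w)
  k <- seq_len(n - 1L)
  diff <- abs(cs[k] / k - (cs[n] - cs[k]) / (n - k))
  eps <- sqrt(log(4 * n / delta) * 0.5 * (1 / k + 1 / (n - k)))
  hit <- which(diff >= eps)
  if (length(hit)) hit[1L] else 0L
}

#' Locate the oldest qualifying split of the current window
#'
#' Scans every split position of the stored window and reports the oldest
#' (smallest index) split at which the absolute difference of the subwindow
#' means reaches the threshold from [epsilon_cut()]. Discarding from the
#' oldest qualifying split onwards, and then re-searching the remainder (as
#' [adwin_update()] does), progressively purges the whole stale regime.
#'
#' @param state An `adwin` detector.
#' @return A list with `cut_found` (logical) and, when a cut exists,
#'   `split_index` (number of elements in `W0`), `mean_w0`, `mean_w1` and
#'   `epsilon` (the threshold at that split).
#' @export
adwin_find_cut <- function(state) {
  stopifnot(inherits(state, "adwin"))
  w <- state$elements
  idx <- find_cut_index(w, state$delta)
  if (idx == 0L) {
    return(list(cut_found = FALSE, split_index = NA_integer_,
                mean_w0 = NA_real_, mean_w1 = NA_real_, epsilon = NA_real_))
  }
  n <- length(w)
  list(
    cut_found = TRUE,
    split_index = idx,
    mean_w0 = mean(w[seq_len(idx)]),
    mean_w1 = mean(w[(idx + 1L):n]),
    epsilon = epsilon_cut(idx, n - idx, n, state$delta)
  )
}

#' Feed one value to an ADWIN detector
#'
#' Appends `value` as the newest window element, then repeatedly searches for
#' a qualifying split: whenever one is found all elements at or before the
#' split are discarded (the older subwindow is dropped and the newer one
#' retained) and the search restarts on the remainder, until no split
#' qualifies. A single update therefore counts at most one drift event even
#' if several truncations were needed.
#'
#' @param state An `adwin` detector.
#' @param value A finite numeric value.
#' @return A list with `state` (the updated detector) and `drift` (logical,
#'   `TRUE` when this update triggered a drift).
#' @examples
#' det <- adwin(0.002)
#' for (x in rnorm(50)) det <- adwin_update(det, x)$state
#' det$drifts_detected
#' @export
adwin_update <- function(state, value) {
  stopifnot(inherits(state, "adwin"))
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    stop("ADWIN update rejected: value is not a finite number (",
         format(value), ")", call. = FALSE)
  }
  w <- c(state$elements, value)
  delta <- state$delta
  drift <- FALSE
  repeat {
    idx <- find_cut_index(w, delta)
    if (idx == 0L) break
    w <- w[(idx + 1L):length(w)]
    drift <- TRUE
  }
  state$elements <- w
  state$total_seen <- state$total_seen + 1L
  if (drift) state$drifts_detected <- state$drifts_detected + 1L
  list(state = state, drift = drift)
}

#' Feed a whole vector through an ADWIN detector
#'
#' Equivalent to calling [adwin_update()] once per element, but with the
#' loop kept internal so long streams are cheap to process. Used by the
#' Analyser agents and by [train_on_chunk()].
#'
#' @param state An `adwin` detector.
#' @param values Finite numeric vector, oldest first.
#' @return A list with `state`, `drift` (logical vector, one flag per input
#'   value) and `positions` (indices into `values` that triggered a drift).
#' @export
adwin_stream <- function(state, values) {
  stopifnot(inherits(state, "adwin"))
  if (length(values) && (!is.numeric(values) || !all(is.finite(values)))) {
    bad <- which(!is.finite(values))[1L]
    stop("ADWIN update rejected: non-finite value at position ", bad,
         call. = FALSE)
  }
  w <- state$elements
  delta <- state$delta
  flags <- logical(length(values))
  ndrift <- 0L
  for (i in seq_along(values)) {
    w <- c(w, values[i])
    hit <- FALSE
    repeat {
      idx <- find_cut_index(w, delta)
      if (idx == 0L) break
      w <- w[(idx + 1L):length(w)]
      hit <- TRUE
    }
    if (hit) {
      flags[i] <- TRUE
      ndrift <- ndrift + 1L
    }
  }
  state$elements <- w
  state$total_seen <- state$total_seen + length(values)
  state$drifts_detected <- state$drifts_detected + ndrift
  list(state = state, drift = flags, positions = which(flags))
}

#' @export
print.adwin <- function(x, ...) {
  cat("<adwin detector>\n")
  cat("  delta:          ", format(x$delta), "\n")
  cat("  window length:  ", length(x$elements), "\n")
  cat("  values seen:    ", x$total_seen, "\n")
  cat("  drifts detected:", x$drifts_detected, "\n")
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' One-row summary of an ADWIN detector
#'
#' @param x An `adwin` detector.
#' @param ... Unused.
#' @return A one-row tibble with the window length, confidence, counts and
#'   current window mean.
#' @export
glance.adwin <- function(x, ...) {
  tibble::tibble(
    n = length(x$elements),
    delta = x$delta,
    total_seen = x$total_seen,
    drifts_detected = x$drifts_detected,
    window_mean = if (length(x$elements)) mean(x$elements) else NA_real_
  )
}

#' Current window of an ADWIN detector as a tibble
#'
#' @param x An `adwin` detector.
#' @param ... Unused.
#' @return A tibble with one row per retained element, oldest first.
#' @export
tidy.adwin <- function(x, ...) {
  tibble::tibble(
    position = seq_along(x$elements),
    value = x$elements
  )
}
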