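#' Describe an injectable drift event
#'
#' Drift events perturb the synthetic EMG stream from `at_ms` onwards on
#' the named channels: `variance_scale` multiplies the noise variance by
#' `magnitude` (the mechanism that matters most in EMG, where drifts show
#' up as variance increases), `mean_shift` offsets the signal by `magnitude`
#' noise standard deviations. Events can be mirrored on a paired channel by
#' listing both channels (left/right limb structure).
#'
#' @param at_ms Onset time in ms (>= 0).
#' @param channels Integer indices of affected channels (non-empty).
#' @param kind `"variance_scale"` or `"mean_shift"`.
#' @param magnitude Variance multiplier (> 0) or offset in sigma units.
#' @param duration_ms Event length in ms; 0 means it persists to the end.
#' @return A `drift_event` list.
#' @export
drift_event <- function(at_ms, channels, kind = c("variance_scale",
                                                  "mean_shift"),
                        magnitude, duration_ms = 0) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(at_ms), at_ms >= 0, length(channels) >= 1,
            is.numeric(duration_ms), duration_ms >= 0)
  if (kind == "variance_scale" && magnitude <= 0) {
    stop("`magnitude` must be > 0 for a variance_scale event",
         call. = FALSE)
  }
  structure(
    list(at_ms = as.numeric(at_ms), channels = as.integer(channels),
         kind = kind, magnitude = as.numeric(magnitude),
         duration_ms = as.numeric(duration_ms)),
    class = "drift_event"
  )
}

default_channel_names <- function(n_channels) {
  if (n_channels == 8L) {
    c("left_bicep", "right_bicep", "left_tricep", "right_tricep",
      "left_thigh", "right_thigh", "left_hamstring", "right_hamstring")
  } else {
    paste0("ch", seq_len(n_channels))
  }
}

#' Configuration of the synthetic EMG generator
#'
#' The generator emulates the structure of an 8-muscle surface-EMG
#' recording sampled at 1 kHz (one row per millisecond): zero-centred,
#' spiky (heavy-tailed) noise per channel, reported as integer microvolt
#' counts, with drift events injectable at chosen times on chosen
#' channels. It does not attempt physiological realism (no motor-unit
#' model); it provides controllable, reproducible inputs for testing the
#' detection stack.
#'
#' @param n_samples Number of rows (milliseconds).
#' @param n_channels Number of channels (default 8).
#' @param base_sigma Noise standard deviation per channel in microvolts
#'   (scalar or length `n_channels`).
#' @param noise `"laplace"` (default; heavy tails emulate EMG spikes) or
#'   `"gaussian"`.
#' @param events List of [drift_event()]s.
#' @param seed Integer seed; generation is fully reproducible.
#' @param channel_names Channel names; defaults to the 8-muscle montage
#'   (left/right bicep, tricep, thigh, hamstring).
#' @param integer_values Round emitted values to integer microvolt counts
#'   (default `TRUE`).
#' @return An `emg_config` list.
#' @export
emg_config <- function(n_samples, n_channels = 8L, base_sigma = 50,
                       noise = c("laplace", "gaussian"), events = list(),
                       seed = 1L,
                       channel_names = default_channel_names(n_channels),
                       integer_values = TRUE) {
  noise <- match.arg(noise)
  stopifnot(is.numeric(n_samples), n_samples >= 1,
            is.numeric(n_channels), n_channels >= 1,
            all(base_sigma >= 0),   # 0 is the degenerate noiseless case
            length(channel_names) == n_channels)
  if (length(base_sigma) == 1L) base_sigma <- rep(base_sigma, n_channels)
  stopifnot(length(base_sigma) == n_channels)
  for (e in events) {
    stopifnot(inherits(e, "drift_event"))
    if (any(e$channels < 1L | e$channels > n_channels)) {
      stop("drift event names a channel outside 1..", n_channels,
           call. = FALSE)
    }
  }
  structure(
    list(n_samples = as.integer(n_samples),
         n_channels = as.integer(n_channels),
         base_sigma = as.numeric(base_sigma), noise = noise,
         events = events, seed = as.integer(seed),
         channel_names = channel_names,
         integer_values = isTRUE(integer_values)),
    class = "emg_config"
  )
}

rlaplace <- function(n, sigma) {
  b <- sigma / sqrt(2)
  u <- stats::runif(n) - 0.5
  -b * sign(u) * log1p(-2 * abs(u))
}

with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic multi-channel EMG stream
#'
#' Draws each channel independently from the configured zero-centred noise
#' law and applies the drift events: within an event's time span, affected
#' channels are recomputed from the same base draws (scaled by
#' `sqrt(magnitude)` for variance events, offset by `magnitude * sigma`
#' for mean shifts), so channels not named in any event are bit-identical
#' to an event-free run with the same seed. When events overlap on a
#' channel the later-listed event wins, with a warning.
#'
#' @param config An [emg_config()].
#' @return A tibble of class `emg_stream`: `time_ms` (0-based, 1 ms per
#'   row) plus one column per channel, in microvolts.
#' @examples
#' cfg <- emg_config(n_samples = 1000, seed = 7,
#'                   events = list(drift_event(500, channels = 5,
#'                                             kind = "variance_scale",
#'                                             magnitude = 4)))
#' x <- emg_generate(cfg)
#' @export
emg_generate <- function(config) {
  stopifnot(inherits(config, "emg_config"))
  n <- config$n_samples
  nc <- config$n_channels
  draw <- switch(config$noise, laplace = rlaplace, gaussian = stats::rnorm)
  base <- with_local_seed(config$seed, {
    vapply(seq_len(nc), function(c) draw(n, config$base_sigma[c]),
           numeric(n))
  })
  base <- matrix(base, nrow = n, ncol = nc)
  out <- base
  owner <- matrix(0L, nrow = n, ncol = nc)
  for (i in seq_along(config$events)) {
    e <- config$events[[i]]
    t0 <- min(n, e$at_ms + 1L)
    t1 <- if (e$duration_ms > 0) min(n, e$at_ms + e$duration_ms) else n
    if (t0 > t1) next
    rows <- t0:t1
    for (ch in e$channels) {
      if (any(owner[rows, ch] > 0L)) {
        warning("overlapping drift events on channel ", ch,
                "; later-listed event wins", call. = FALSE)
      }
      out[rows, ch] <- switch(
        e$kind,
        variance_scale = sqrt(e$magnitude) * base[rows, ch],
        mean_shift = base[rows, ch] +
          e$magnitude * config$base_sigma[ch]
      )
      owner[rows, ch] <- i
    }
  }
  if (config$integer_values) out <- round(out)
  colnames(out) <- config$channel_names
  res <- tibble::as_tibble(out)
  res <- tibble::add_column(res, time_ms = 0:(n - 1L), .before = 1L)
  class(res) <- c("emg_stream", class(res))
  attr(res, "config") <- config
  res
}

#' Write a stream as a headerless delimited file
#'
#' Emits the UCI physical-action dialect: one row per time step, one
#' numeric column per channel, no header. The `time_ms` column of an
#' `emg_stream` is implicit (1 ms per row) and not written.
#'
#' @param x An `emg_stream` tibble, data frame, or numeric matrix.
#' @param path Output path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
emg_write_csv <- function(x, path, delim = ",") {
  m <- as.data.frame(x)
  m$time_ms <- NULL
  stopifnot(all(vapply(m, is.numeric, logical(1))))
  if (!all(vapply(m, function(col) all(is.finite(col)), logical(1)))) {
    stop("matrix contains non-finite values", call. = FALSE)
  }
  utils::write.table(m, path, sep = delim, col.names = FALSE,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a headerless delimited multi-channel recording
#'
#' Accepts comma-, tab- or whitespace-delimited files (auto-detected).
#' Rows whose column count differs from `n_channels`, or that contain a
#' non-numeric cell, are skipped; each skipped row is reported with its
#' line number via a warning and in the `skipped` attribute of the result.
#'
#' @param path Input path.
#' @param n_channels Expected number of columns (default 8).
#' @param channel_names Optional column names; default `ch1..chN`.
#' @return A tibble with one column per channel and attribute `skipped`
#'   (tibble of `line`, `reason`).
#' @export
emg_read_csv <- function(path, n_channels = 8L,
                         channel_names = paste0("ch", seq_len(n_channels))) {
  if (!file.exists(path)) {
    stop("cannot read input file: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    out <- tibble::as_tibble(matrix(numeric(0), ncol = n_channels,
                                    dimnames = list(NULL, channel_names)))
    attr(out, "skipped") <- tibble::tibble(line = integer(0),
                                           reason = character(0))
    return(out)
  }
  probe <- lines[1L]
  delim <- if (grepl("\t", probe, fixed = TRUE)) "\t"
           else if (grepl(",", probe, fixed = TRUE)) ","
           else "[[:space:]]+"
  fields <- strsplit(trimws(lines), delim)
  nf <- lengths(fields)
  bad_count <- nf != n_channels
  vals <- suppressWarnings(
    lapply(fields, function(f) as.numeric(f))
  )
  bad_parse <- !bad_count &
    vapply(vals, anyNA, logical(1))
  bad <- bad_count | bad_parse
  skipped <- tibble::tibble(
    line = line_no[bad],
    reason = ifelse(bad_count[bad],
                    paste0("expected ", n_channels, " columns, found ",
                           nf[bad]),
                    "non-numeric cell")
  )
  if (nrow(skipped)) {
    warning("skipped ", nrow(skipped), " malformed row(s) at line(s) ",
            paste(utils::head(skipped$line, 10L), collapse = ", "),
            if (nrow(skipped) > 10L) ", ..." else "", call. = FALSE)
  }
  good <- vals[!bad]
  m <- if (length(good)) {
    matrix(unlist(good), ncol = n_channels, byrow = TRUE)
  } else {
    matrix(numeric(0), ncol = n_channels)
  }
  colnames(m) <- channel_names
  out <- tibble::as_tibble(m)
  attr(out, "skipped") <- skipped
  out
}
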