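#' Canonical JSON serialization
#'
#' Serializes a payload to JSON with object keys sorted recursively and no
#' insignificant whitespace, so that equal payloads are byte-identical after
#' a round trip through the Knowledge Base. A character input must itself be
#' valid JSON and is re-canonicalized.
#'
#' @param x A named list (JSON object), scalar, or a JSON string.
#' @return A single JSON string.
#' @examples
#' canonical_json(list(sensor = 429))
#' canonical_json('{"b": 1, "a": 2}')
#' @export
canonical_json <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!jsonlite::validate(x)) {
      stop("`data` is not valid JSON: ", substr(x, 1, 60), call. = FALSE)
    }
    x <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  }
  sort_rec <- function(v) {
    if (is.list(v)) {
      nm <- names(v)
      if (!is.null(nm) && any(nzchar(nm))) v <- v[order(nm)]
      lapply(v, sort_rec)
    } else {
      v
    }
  }
  as.character(jsonlite::toJSON(sort_rec(x), auto_unbox = TRUE, digits = NA))
}

parse_kb_time <- function(x, what = "timestamp") {
  if (inherits(x, "POSIXct")) return(x)
  if (is.character(x)) {
    out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%OS")
    if (any(is.na(out))) {
      stop("cannot parse ", what, ": ", x[which(is.na(out))[1L]],
           call. = FALSE)
    }
    return(out)
  }
  if (is.numeric(x)) {
    return(as.POSIXct(x, origin = "1970-01-01", tz = "UTC"))
  }
  stop("`", what, "` must be a POSIXct, an ISO-8601 string, or numeric",
       call. = FALSE)
}

#' Build a validated Knowledge Base prediction record
#'
#' One record per analysed sample: who analysed it (`jid`), the monitored
#' payload as canonical JSON (`data`), when it was collected and analysed,
#' which channel it belongs to (`identifier`) and the boolean drift verdict
#' (`predicted`).
#'
#' @param jid Analyser name.
#' @param data Payload: named list or JSON string, e.g. `list(sensor = 429)`.
#' @param datetime_monitored,datetime_analysed POSIXct or
#'   `"YYYY-MM-DD HH:MM:SS[.mmm]"` strings; `datetime_analysed` must not
#'   precede `datetime_monitored`.
#' @param identifier Non-empty channel name, e.g. `"left_thigh"`.
#' @param predicted Single non-NA logical.
#' @return A one-row tibble of class `prediction_record`.
#' @export
prediction_record <- function(jid, data, datetime_monitored,
                              datetime_analysed, identifier, predicted) {
  if (!is.character(jid) || length(jid) != 1L || !nzchar(jid)) {
    stop("`jid` must be a non-empty string", call. = FALSE)
  }
  if (!is.character(identifier) || length(identifier) != 1L ||
      !nzchar(identifier)) {
    stop("`identifier` must be a non-empty string", call. = FALSE)
  }
  if (!is.logical(predicted) || length(predicted) != 1L || is.na(predicted)) {
    stop("`predicted` must be a single TRUE or FALSE", call. = FALSE)
  }
  mon <- parse_kb_time(datetime_monitored, "datetime_monitored")
  ana <- parse_kb_time(datetime_analysed, "datetime_analysed")
  if (as.numeric(ana) < as.numeric(mon)) {
    stop("`datetime_analysed` precedes `datetime_monitored`", call. = FALSE)
  }
  out <- tibble::tibble(
    jid = jid,
    data = canonical_json(data),
    datetime_monitored = mon,
    datetime_analysed = ana,
    identifier = identifier,
    predicted = predicted
  )
  class(out) <- c("prediction_record", class(out))
  out
}

#' Open a Knowledge Base
#'
#' The Knowledge Base is the shared store of the MAPE-K loop: every
#' prediction made by an Analyser is appended here and later read back by
#' the Planner (decision windows) and by the Analysers themselves
#' (retraining). Two backends implement the same append-only table
#' `predictions(jid, data, datetime_monitored, datetime_analysed,
#' identifier, predicted)` plus an auto-increment surrogate key `id`:
#'
#' * `"memory"` — an in-process column store (fast, per-session);
#' * `"file"` — a single tab-delimited file with ISO-8601 millisecond
#'   timestamps (durable, zero-install).
#'
#' @param backend `"memory"` or `"file"`.
#' @param path File path, required for the file backend.
#' @return A `driftwatch_kb` handle.
#' @export
kb_connect <- function(backend = c("memory", "file"), path = NULL) {
  backend <- match.arg(backend)
  env <- new.env(parent = emptyenv())
  env$backend <- backend
  if (backend == "memory") {
    env$n <- 0L
    env$cap <- 0L
    for (col in c("jid", "data", "identifier")) assign(col, character(0), env)
    env$mon <- numeric(0)
    env$ana <- numeric(0)
    env$pred <- logical(0)
    class(env) <- c("kb_memory", "driftwatch_kb")
  } else {
    if (is.null(path)) stop("file backend requires `path`", call. = FALSE)
    env$path <- path
    if (!file.exists(path)) {
      cat(paste(c("id", "jid", "data", "datetime_monitored",
                  "datetime_analysed", "identifier", "predicted"),
                collapse = "\t"), "\n", sep = "", file = path)
    }
    class(env) <- c("kb_file", "driftwatch_kb")
  }
  env
}

validate_record_frame <- function(df) {
  need <- c("jid", "data", "datetime_monitored", "datetime_analysed",
            "identifier", "predicted")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("record is missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!is.logical(df$predicted) || anyNA(df$predicted)) {
    stop("`predicted` must be strictly boolean", call. = FALSE)
  }
  if (any(!nzchar(df$identifier)) || anyNA(df$identifier)) {
    stop("`identifier` must be non-empty", call. = FALSE)
  }
  mon <- as.numeric(parse_kb_time(df$datetime_monitored))
  ana <- as.numeric(parse_kb_time(df$datetime_analysed))
  if (any(ana < mon)) {
    stop("`datetime_analysed` precedes `datetime_monitored` in ",
         sum(ana < mon), " record(s); insert rejected", call. = FALSE)
  }
  ok <- vapply(df$data, jsonlite::validate, logical(1), USE.NAMES = FALSE)
  if (!all(ok)) {
    stop("`data` is not valid JSON in ", sum(!ok), " record(s)",
         call. = FALSE)
  }
  df
}

#' Append prediction records to the Knowledge Base
#'
#' Inserts are append-only; there are no updates or deletes. Records failing
#' the schema invariants (boolean verdict, non-empty identifier, valid JSON
#' payload, analysis time not before monitoring time) are rejected before
#' anything is written.
#'
#' @param kb A `driftwatch_kb` handle from [kb_connect()].
#' @param records A [prediction_record()] or a tibble of records (bulk
#'   insert).
#' @return Invisibly, the number of records inserted.
#' @export
kb_insert <- function(kb, records) {
  stopifnot(inherits(kb, "driftwatch_kb"))
  df <- validate_record_frame(tibble::as_tibble(records))
  mon <- as.numeric(parse_kb_time(df$datetime_monitored))
  ana <- as.numeric(parse_kb_time(df$datetime_analysed))
  n <- nrow(df)
  if (n == 0L) return(invisible(0L))
  if (inherits(kb, "kb_memory")) {
    need <- kb$n + n
    if (need > kb$cap) {
      newcap <- max(1024L, 2L * need)
      length(kb$jid) <- newcap
      length(kb$data) <- newcap
      length(kb$identifier) <- newcap
      length(kb$mon) <- newcap
      length(kb$ana) <- newcap
      length(kb$pred) <- newcap
      kb$cap <- newcap
    }
    i <- (kb$n + 1L):need
    kb$jid[i] <- df$jid
    kb$data[i] <- df$data
    kb$identifier[i] <- df$identifier
    kb$mon[i] <- mon
    kb$ana[i] <- ana
    kb$pred[i] <- df$predicted
    kb$n <- need
  } else {
    ids <- kb_count(kb) + seq_len(n)
    lines <- paste(ids, df$jid, df$data,
                   format_kb_time(mon), format_kb_time(ana),
                   df$identifier, ifelse(df$predicted, "TRUE", "FALSE"),
                   sep = "\t")
    cat(lines, sep = "\n", file = kb$path, append = TRUE)
  }
  invisible(n)
}

format_kb_time <- function(num) {
  # explicit millisecond arithmetic: %OS3 truncates instead of rounding
  ms <- round(num * 1000)
  t <- as.POSIXct(ms %/% 1000, origin = "1970-01-01", tz = "UTC")
  sprintf("%s.%03d", format(t, "%Y-%m-%d %H:%M:%S", tz = "UTC"), ms %% 1000)
}

#' All Knowledge Base records as a tibble
#'
#' @param kb A `driftwatch_kb` handle.
#' @return A tibble with the surrogate key `id` plus the schema columns, in
#'   insertion order.
#' @export
kb_records <- function(kb) {
  stopifnot(inherits(kb, "driftwatch_kb"))
  if (inherits(kb, "kb_memory")) {
    i <- seq_len(kb$n)
    tibble::tibble(
      id = i,
      jid = kb$jid[i],
      data = kb$data[i],
      datetime_monitored = as.POSIXct(kb$mon[i], origin = "1970-01-01",
                                      tz = "UTC"),
      datetime_analysed = as.POSIXct(kb$ana[i], origin = "1970-01-01",
                                     tz = "UTC"),
      identifier = kb$identifier[i],
      predicted = kb$pred[i]
    )
  } else {
    df <- utils::read.delim(kb$path, stringsAsFactors = FALSE,
                            colClasses = c("integer", "character",
                                           "character", "character",
                                           "character", "character",
                                           "character"),
                            quote = "", check.names = FALSE)
    tibble::tibble(
      id = df$id,
      jid = df$jid,
      data = df$data,
      datetime_monitored = parse_kb_time(df$datetime_monitored),
      datetime_analysed = parse_kb_time(df$datetime_analysed),
      identifier = df$identifier,
      predicted = df$predicted == "TRUE"
    )
  }
}

#' Number of records in the Knowledge Base
#' @param kb A `driftwatch_kb` handle.
#' @return Integer count.
#' @export
kb_count <- function(kb) {
  stopifnot(inherits(kb, "driftwatch_kb"))
  if (inherits(kb, "kb_memory")) return(kb$n)
  max(0L, length(readLines(kb$path, warn = FALSE)) - 1L)
}

#' Query records analysed inside a time window
#'
#' Returns all records with `since < datetime_analysed <= until`, optionally
#' restricted to positive drift verdicts, ordered by analysis time then
#' analyser name. This is the Planner's query pattern.
#'
#' @param kb A `driftwatch_kb` handle.
#' @param since,until Window bounds (POSIXct, string, or numeric seconds);
#'   `since` must not exceed `until`.
#' @param predicted_only If `TRUE`, keep only records with
#'   `predicted = TRUE`.
#' @return A tibble of records.
#' @export
kb_query_window <- function(kb, since, until, predicted_only = FALSE) {
  since <- as.numeric(parse_kb_time(since, "since"))
  until <- as.numeric(parse_kb_time(until, "until"))
  if (since > until) stop("`since` must not exceed `until`", call. = FALSE)
  recs <- kb_records(kb)
  ana <- as.numeric(recs$datetime_analysed)
  out <- recs[ana > since & ana <= until, , drop = FALSE]
  if (predicted_only) out <- out[out$predicted, , drop = FALSE]
  dplyr::arrange(out, .data$datetime_analysed, .data$jid)
}

#' Query the most recent records for one channel
#'
#' Returns the most recent `limit` records for `identifier`, oldest first —
#' the Analyser's retraining query pattern. An unknown identifier yields an
#' empty result.
#'
#' @param kb A `driftwatch_kb` handle.
#' @param identifier Channel name.
#' @param limit Maximum number of records; `Inf` for all.
#' @return A tibble of records, oldest first.
#' @export
kb_query_training <- function(kb, identifier, limit = Inf) {
  recs <- kb_records(kb)
  out <- recs[recs$identifier == identifier, , drop = FALSE]
  out <- dplyr::arrange(out, .data$id)
  if (is.finite(limit) && nrow(out) > limit) {
    out <- out[(nrow(out) - limit + 1L):nrow(out), , drop = FALSE]
  }
  out
}

#' @export
print.driftwatch_kb <- function(x, ...) {
  cat("<knowledge base: ", x$backend, " backend, ", kb_count(x),
      " record(s)>\n", sep = "")
  invisible(x)
}
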